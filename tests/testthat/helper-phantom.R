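# Shared fixtures: small phantom configurations and constructed masks.
# Grids are kept small so unit tests stay fast; the acceptance tests use
# the full 32x64x64 study grid.

tiny_config <- function(...) {
  phantomConfig(gridShape = c(16, 24, 24), spacing = c(5, 2, 2),
                lesionRadiusRange = c(3.5, 6), ...)
}

micro_config <- function(...) {
  phantomConfig(gridShape = c(12, 16, 16), spacing = c(5, 2.5, 2.5),
                nPelvic = 1, nOmental = 1,
                lesionRadiusRange = c(3, 4.5), ...)
}

# normalised training-ready pair from a generated case
as_training_pair <- function(case) {
  longitudinalPair(clipAndNormalize(baseline(case)),
                   clipAndNormalize(followup(case)),
                   baselineMask = baselineMask(case),
                   followupMask = followupMask(case),
                   response = responseLabel(case),
                   recist = recistCategory(case))
}

tiny_training_pairs <- function(n, config = micro_config(), seed = 11) {
  flags <- rep_len(c(1L, 0L), n)
  lapply(seq_len(n), function(i)
    as_training_pair(generateCase(config, flags[i],
                                  rngSeed = seed + 131L * i)))
}

# axis-aligned ellipsoid mask built directly in mm coordinates
ellipsoid_mask <- function(dims, spacing, centre, radii, label = 2L) {
  arr <- array(0L, dims)
  cc <- lapply(1:3, function(a)
    (seq_len(dims[a]) - 1 - (dims[a] - 1) / 2) * spacing[a])
  for (k in seq_len(dims[3])) for (j in seq_len(dims[2]))
    for (i in seq_len(dims[1])) {
      if (sum(((c(cc[[1]][i], cc[[2]][j], cc[[3]][k]) - centre) /
                 radii)^2) <= 1)
        arr[i, j, k] <- label
    }
  labelMask(arr, spacing)
}

tiny_net_config <- function(...) {
  base <- list(nLevels = 3, baseChannels = 4, channelCap = 16,
               dropoutP = 0.1)
  do.call(networkConfig, utils::modifyList(base, list(...)))
}
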