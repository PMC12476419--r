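# Run code with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Row-wise softmax of an N x C matrix, numerically stabilised.
softmax_rows <- function(z) {
  mx <- z[, 1]
  for (j in seq_len(ncol(z))[-1]) mx <- pmax(mx, z[, j])
  e <- exp(z - mx)
  e / rowSums(e)
}

# One-hot encode integer labels (0-based) into an N x C matrix.
onehot_rows <- function(labels, nClasses) {
  n <- length(labels)
  m <- matrix(0, n, nClasses)
  m[cbind(seq_len(n), labels + 1L)] <- 1
  m
}

# Nearest-neighbour downsampling of an integer label array to `odims`
# (align-corners = FALSE convention, matching the trilinear resizer).
nn_resize_labels <- function(arr, odims) {
  d <- dim(arr)
  idx <- lapply(1:3, function(a) {
    i <- round((seq_len(odims[a]) - 0.5) * d[a] / odims[a] + 0.5 - 1e-9)
    pmin(pmax(i, 1L), d[a])
  })
  arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

# feature-map helpers: maps are arrays (D, H, W, C)
fm_nvox <- function(x) prod(dim(x)[1:3])
fm_mat <- function(x) {
  d <- dim(x)
  dim(x) <- c(prod(d[1:3]), d[4])
  x
}
mat_fm <- function(m, sdims) {
  dim(m) <- c(sdims, ncol(m))
  m
}
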