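#' Configuration for the synthetic longitudinal phantom
#'
#' The phantom emulates paired abdominal CT at the level of detail the
#' downstream network needs: an elliptical soft-tissue body cross-section
#' in air, two disjoint anatomical regions (caudal slices for
#' pelvic/ovarian disease, ventral-cranial slices for omental disease),
#' and ellipsoidal lesions with positive HU contrast over soft tissue
#' whose in-plane diameters change between time points according to
#' RECIST 1.1 responder / non-responder rules.
#'
#' @param gridShape integer(3) voxels per axis (slice, row, column).
#' @param spacing numeric(3) voxel spacing in mm.
#' @param nPelvic,nOmental lesion counts per region.
#' @param lesionRadiusRange numeric(2), base lesion radius range in mm.
#' @param lesionHuRange numeric(2), lesion attenuation range in HU.
#' @param bodyHu soft-tissue attenuation in HU.
#' @param backgroundHu air attenuation in HU.
#' @param noiseSd Gaussian noise standard deviation in HU (independently
#'   drawn per time point; clamped at 4 sd so intensities stay bounded).
#' @param responderFraction proportion of responders in a cohort.
#' @param seed integer seed for cohort generation.
#' @return A \code{PhantomConfig} list.
#' @export
phantomConfig <- function(gridShape = c(32, 64, 64),
                          spacing = c(5, 0.8, 0.8), nPelvic = 2,
                          nOmental = 2, lesionRadiusRange = c(3.5, 7),
                          lesionHuRange = c(90, 140), bodyHu = 40,
                          backgroundHu = -1000, noiseSd = 15,
                          responderFraction = 0.5, seed = 1L) {
  stopifnot(length(gridShape) == 3L, all(gridShape >= 8),
            length(spacing) == 3L, all(spacing > 0),
            nPelvic >= 0, nOmental >= 0,
            length(lesionRadiusRange) == 2L,
            all(lesionRadiusRange > 0),
            lesionRadiusRange[1] <= lesionRadiusRange[2],
            lesionHuRange[1] <= lesionHuRange[2], noiseSd >= 0,
            responderFraction >= 0, responderFraction <= 1)
  structure(list(gridShape = as.integer(gridShape),
                 spacing = as.numeric(spacing),
                 nPelvic = as.integer(nPelvic),
                 nOmental = as.integer(nOmental),
                 lesionRadiusRange = lesionRadiusRange,
                 lesionHuRange = lesionHuRange, bodyHu = bodyHu,
                 backgroundHu = backgroundHu, noiseSd = noiseSd,
                 responderFraction = responderFraction,
                 seed = as.integer(seed)),
            class = "PhantomConfig")
}

# physical coordinates (mm) of voxel centres about the grid centre
phantom_coords <- function(config) {
  d <- config$gridShape; sp <- config$spacing
  lapply(1:3, function(a) (seq_len(d[a]) - 1 - (d[a] - 1) / 2) * sp[a])
}

# body semi-axes (mm): an eccentric ellipsoid (wider than deep, tapering
# towards both ends of the scan range) so that all six rigid degrees of
# freedom are anatomically identifiable
phantom_body_axes <- function(config) {
  d <- config$gridShape; sp <- config$spacing
  c(slice = 0.52 * d[1] * sp[1], row = 0.35 * d[2] * sp[2],
    col = 0.47 * d[3] * sp[3])
}

phantom_body <- function(config) {
  cc <- phantom_coords(config)
  ax <- phantom_body_axes(config)
  r2 <- outer((cc[[1]] / ax[1])^2,
              outer((cc[[2]] / ax[2])^2, (cc[[3]] / ax[3])^2, `+`), `+`)
  body <- array(config$backgroundHu, config$gridShape)
  body[r2 <= 1] <- config$bodyHu
  body
}

# slice-axis extent (fractions of the grid) of the two disease regions
phantom_regions <- list(pelvic = c(0.55, 0.92), omental = c(0.08, 0.45))

# Sample one lesion: centre (mm), per-axis radii (mm).  `grow` reserves
# headroom inside the body for later diameter growth (PD cases).
place_lesion <- function(config, region, grow = 1.65, maxTries = 400L) {
  d <- config$gridShape; sp <- config$spacing
  ax <- phantom_body_axes(config)
  zr <- phantom_regions[[region]]
  zlim <- ((zr * (d[1] - 1)) - (d[1] - 1) / 2) * sp[1]
  for (i in seq_len(maxTries)) {
    rb <- runif(1, config$lesionRadiusRange[1],
                config$lesionRadiusRange[2])
    rad <- rb * runif(3, 0.85, 1.2)
    cz <- runif(1, zlim[1], zlim[2])
    # omental disease sits against the ventral (anterior) wall, the
    # pelvic/ovarian sites centrally/dorsally: negative rows = anterior
    crow <- if (region == "omental") runif(1, -0.55 * ax[2],
                                           -0.1 * ax[2])
    else runif(1, -0.1 * ax[2], 0.55 * ax[2])
    ccol <- runif(1, -0.6 * ax[3], 0.6 * ax[3])
    # the lesion (with growth headroom) must stay inside the body
    # ellipsoid and inside its slice band
    fit <- (abs(cz) + grow * rad[1])^2 / ax[1]^2 +
      (abs(crow) + grow * rad[2])^2 / ax[2]^2 +
      (abs(ccol) + grow * rad[3])^2 / ax[3]^2 <= 0.92
    fit_z <- (cz - grow * rad[1]) >= zlim[1] - sp[1] &&
      (cz + grow * rad[1]) <= zlim[2] + sp[1]
    if (fit && fit_z)
      return(list(centre = c(cz, crow, ccol), radii = rad))
  }
  stop("failed to place a lesion in the ", region,
       " region after ", maxTries, " attempts")
}

# Paint lesions (scaled by `scales`) onto a body volume; returns volume
# (HU, no noise) and mask.
paint_lesions <- function(config, body, lesions, scales) {
  cc <- phantom_coords(config)
  vol <- body
  mask <- array(0L, config$gridShape)
  for (i in seq_along(lesions)) {
    le <- lesions[[i]]
    s <- scales[i]
    if (s <= 0) next
    rad <- le$radii * s
    idx <- lapply(1:3, function(a)
      which(abs(cc[[a]] - le$centre[a]) <= rad[a] + config$spacing[a]))
    if (any(lengths(idx) == 0)) next
    dz <- (cc[[1]][idx[[1]]] - le$centre[1]) / rad[1]
    dr <- (cc[[2]][idx[[2]]] - le$centre[2]) / rad[2]
    dc <- (cc[[3]][idx[[3]]] - le$centre[3]) / rad[3]
    inside <- outer(outer(dz^2, dr^2, `+`), dc^2, `+`) <= 1
    if (!any(inside)) next
    sub <- vol[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    sub[inside] <- le$hu
    vol[idx[[1]], idx[[2]], idx[[3]]] <- sub
    msub <- mask[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    msub[inside] <- le$class
    mask[idx[[1]], idx[[2]], idx[[3]]] <- msub
  }
  list(vol = vol, mask = mask)
}

add_noise <- function(x, sd) {
  if (sd <= 0) return(x)
  n <- pmin(pmax(rnorm(length(x), 0, sd), -4 * sd), 4 * sd)
  x + array(n, dim(x))
}

#' RECIST 1.1 response category from a pair of lesion masks
#'
#' Measures every lesion (each connected component of the omental and
#' pelvic/ovarian classes) by its longest in-plane diameter -- the
#' maximum pairwise distance between voxel centres within any single
#' slice, matching measurement on axial CT -- and classifies the change
#' in the sum of diameters by RECIST 1.1 thresholds: CR when no residual
#' lesion remains, PR when the sum decreases by at least 30\%, PD when it
#' increases by at least 20\%, SD otherwise.  The binary response label
#' is 1 (responder) for CR or PR.
#'
#' @param baselineMask,followupMask aligned
#'   \code{\linkS4class{LabelMask}} objects on the same spacing.
#' @return A list with \code{category} ("CR", "PR", "SD" or "PD"),
#'   \code{response} (integer 0/1), and the measured \code{baselineSum}
#'   and \code{followupSum} of diameters in mm.
#' @export
recistLabel <- function(baselineMask, followupMask) {
  sb <- voxelSpacing(baselineMask); sf <- voxelSpacing(followupMask)
  if (max(abs(sb - sf)) > 1e-9)
    stop("masks must share the same voxel spacing")
  if (!identical(dim(volData(baselineMask)), dim(volData(followupMask))))
    stop("masks must share the same grid")
  sumB <- sum_of_diameters(baselineMask)
  if (sumB <= 0)
    stop("no measurable disease in the baseline mask")
  sumF <- sum_of_diameters(followupMask)
  if (sumF == 0) {
    cat_ <- "CR"
  } else {
    ratio <- sumF / sumB
    cat_ <- if (ratio <= 0.7) "PR" else if (ratio >= 1.2) "PD" else "SD"
  }
  list(category = cat_, response = as.integer(cat_ %in% c("CR", "PR")),
       baselineSum = sumB, followupSum = sumF)
}

# Sum over all lesions of the longest in-plane diameter (mm).
sum_of_diameters <- function(mask) {
  arr <- volData(mask); sp <- voxelSpacing(mask)
  total <- 0
  for (cls in c(1L, 2L)) {
    comp <- array(cpp_label_components(as.integer(arr), dim(arr), cls),
                  dim(arr))
    ncomp <- max(comp)
    if (ncomp == 0) next
    ext <- mean(sp[2:3])   # in-plane voxel extent: floor for the
                           # diameter of a single-voxel cross-section
    for (k in seq_len(ncomp)) {
      vox <- which(comp == k, arr.ind = TRUE)
      dia <- 0
      for (sl in unique(vox[, 1])) {
        pts <- vox[vox[, 1] == sl, 2:3, drop = FALSE]
        pts <- cbind(pts[, 1] * sp[2], pts[, 2] * sp[3])
        if (nrow(pts) > 3) pts <- pts[grDevices::chull(pts), ,
                                      drop = FALSE]
        span <- if (nrow(pts) >= 2) max(stats::dist(pts)) else 0
        dia <- max(dia, span + ext)
      }
      total <- total + dia
    }
  }
  total
}

draw_scales <- function(category, diams) {
  n <- length(diams)
  if (category == "CR") return(rep(0, n))
  target <- switch(category,
                   PR = runif(1, 0.45, 0.65),
                   SD = runif(1, 0.85, 1.10),
                   PD = runif(1, 1.28, 1.45))
  het <- switch(category, PR = 0.25, SD = 0.06, PD = 0.06)
  s <- target * exp(runif(n, -het, het))
  # renormalise so the diameter-weighted mean scale hits the target
  s <- s * target / (sum(diams * s) / sum(diams))
  pmin(pmax(s, 0.05), 1.6)
}

#' Generate one synthetic longitudinal case
#'
#' Builds a baseline phantom with the configured lesion counts, then a
#' follow-up in which each lesion's diameter is rescaled by an
#' independent per-lesion factor constrained to a case-level RECIST
#' category consistent with the requested responder status (responders
#' receive a PR-scale shrinkage, occasionally a CR with all lesions
#' removed; non-responders an SD or PD change).  Gaussian HU noise is
#' added independently per time point.  The stored label is always
#' recomputed from the emitted masks via \code{\link{recistLabel}},
#' never assumed.
#'
#' @param config a \code{\link{phantomConfig}}.
#' @param responder logical or 0/1; generate a responder case.
#' @param rngSeed integer seed; the same seed reproduces the case
#'   bit-identically.
#' @return A labelled \code{\linkS4class{LongitudinalPair}} with volumes
#'   in Hounsfield units.
#' @export
generateCase <- function(config, responder, rngSeed) {
  stopifnot(inherits(config, "PhantomConfig"))
  if (config$nPelvic + config$nOmental == 0)
    stop("no measurable disease: lesion counts are both zero")
  responder <- as.integer(responder)
  with_seed(rngSeed, {
    body <- phantom_body(config)
    for (attempt in seq_len(25L)) {
      lesions <- c(
        lapply(seq_len(config$nOmental), function(i) {
          le <- place_lesion(config, "omental")
          le$class <- 1L
          le$hu <- runif(1, config$lesionHuRange[1],
                         config$lesionHuRange[2])
          le
        }),
        lapply(seq_len(config$nPelvic), function(i) {
          le <- place_lesion(config, "pelvic")
          le$class <- 2L
          le$hu <- runif(1, config$lesionHuRange[1],
                         config$lesionHuRange[2])
          le
        }))
      category <- if (responder == 1L) {
        if (runif(1) < 0.2) "CR" else "PR"
      } else {
        if (runif(1) < 0.5) "SD" else "PD"
      }
      diams <- vapply(lesions, function(le) 2 * max(le$radii[2:3]),
                      numeric(1))
      scales <- draw_scales(category, diams)
      bl <- paint_lesions(config, body, lesions, rep(1, length(lesions)))
      fu <- paint_lesions(config, body, lesions, scales)
      blMask <- labelMask(bl$mask, config$spacing)
      fuMask <- labelMask(fu$mask, config$spacing)
      lab <- tryCatch(recistLabel(blMask, fuMask),
                      error = function(e) NULL)
      if (is.null(lab) || lab$response != responder) next
      blVol <- ctVolume(add_noise(bl$vol, config$noiseSd),
                        config$spacing)
      fuVol <- ctVolume(add_noise(fu$vol, config$noiseSd),
                        config$spacing)
      return(longitudinalPair(blVol, fuVol, baselineMask = blMask,
                              followupMask = fuMask,
                              response = lab$response,
                              recist = lab$category))
    }
    stop("failed to generate a case with the requested response after ",
         "25 attempts")
  })
}

#' Generate a synthetic cohort on disk
#'
#' Draws responder status per case from
#' \code{config$responderFraction}, writes the NIfTI volumes and masks
#' of every case under \code{outDir}, and returns the cohort manifest
#' (also written as \code{manifest.csv}).
#'
#' @param config a \code{\link{phantomConfig}}; \code{config$seed}
#'   drives all randomness.
#' @param nCases number of cases (>= 1).
#' @param outDir output directory (created if missing).
#' @return The manifest data frame with columns \code{case_id},
#'   \code{baseline_path}, \code{followup_path},
#'   \code{baseline_mask_path}, \code{followup_mask_path},
#'   \code{recist}, \code{response}.
#' @export
generateCohort <- function(config, nCases, outDir) {
  stopifnot(inherits(config, "PhantomConfig"), nCases >= 1)
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outDir)
  flags <- with_seed(config$seed,
                     rbinom(nCases, 1, config$responderFraction))
  rows <- vector("list", nCases)
  for (i in seq_len(nCases)) {
    case <- generateCase(config, flags[i],
                         rngSeed = (config$seed + 7919L * i) %%
                           .Machine$integer.max)
    id <- sprintf("case_%04d", i)
    paths <- file.path(outDir, paste0(id, c("_bl.nii.gz", "_fu.nii.gz",
                                            "_bl_mask.nii.gz",
                                            "_fu_mask.nii.gz")))
    writeVolume(baseline(case), paths[1])
    writeVolume(followup(case), paths[2])
    writeVolume(baselineMask(case), paths[3])
    writeVolume(followupMask(case), paths[4])
    rows[[i]] <- data.frame(case_id = id, baseline_path = paths[1],
                            followup_path = paths[2],
                            baseline_mask_path = paths[3],
                            followup_mask_path = paths[4],
                            recist = recistCategory(case),
                            response = responseLabel(case),
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(outDir, "manifest.csv"),
            row.names = FALSE)
  manifest
}
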