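#' Clip Hounsfield units and rescale to [0, 1]
#'
#' Attenuation-clips a CT volume to the soft-tissue window
#' \eqn{[-150, 250]} HU (boundaries inclusive) and maps it linearly onto
#' \eqn{[0, 1]}: \eqn{v \mapsto (\min(\max(v, -150), 250) + 150) / 400}.
#' Applying it twice is a state error, guarded by the volume's
#' \code{normalised} flag.
#'
#' @param vol a \code{\linkS4class{CTVolume}} in Hounsfield units.
#' @param clipLo,clipHi clip window in HU.
#' @return A normalised \code{CTVolume} with values in \eqn{[0, 1]}.
#' @examples
#' v <- ctVolume(array(c(-1000, 50, 250), c(3, 1, 1)))
#' volData(clipAndNormalize(v))  # 0, 0.5, 1
#' @export
clipAndNormalize <- function(vol, clipLo = -150, clipHi = 250) {
  if (isNormalised(vol))
    stop("volume is already normalised; refusing to normalise twice")
  x <- pmin(pmax(volData(vol), clipLo), clipHi)
  x <- (x - clipLo) / (clipHi - clipLo)
  ctVolume(array(x, dim(x)), voxelSpacing(vol), normalised = TRUE)
}

#' Resample a volume or mask to a target voxel spacing
#'
#' Images are interpolated trilinearly, masks by nearest neighbour (so the
#' label set can never grow).  The grid is resampled about its physical
#' centre; the output grid shape is \code{round(dim * spacing / target)}.
#'
#' @param vol a \code{\linkS4class{CTVolume}} or
#'   \code{\linkS4class{LabelMask}}.
#' @param targetSpacing numeric(3) target spacing in mm
#'   (slice, row, column).
#' @return The resampled object with spacing equal to
#'   \code{targetSpacing}.
#' @export
resampleVolume <- function(vol, targetSpacing = c(5, 0.8, 0.8)) {
  targetSpacing <- as.numeric(targetSpacing)
  if (length(targetSpacing) != 3L || any(targetSpacing <= 0))
    stop("target spacing must be three strictly positive values")
  isMask <- is(vol, "LabelMask")
  x <- volData(vol)
  sp <- voxelSpacing(vol)
  odims <- pmax(1L, as.integer(round(dim(x) * sp / targetSpacing)))
  out <- cpp_resample_affine(as.double(x), dim(x), sp, diag(3),
                             numeric(3), odims, targetSpacing,
                             nearest = isMask, fill = min(x))
  out <- array(out, odims)
  if (isMask) labelMask(array(as.integer(round(out)), odims),
                        targetSpacing)
  else ctVolume(out, targetSpacing, normalised = isNormalised(vol))
}

rigid_matrix <- function(par) {
  # par = (rot slice, rot row, rot col) in degrees, then translations mm
  a <- par[1:3] * pi / 180
  cd <- cos(a[1]); sd <- sin(a[1])
  ch <- cos(a[2]); sh <- sin(a[2])
  cw <- cos(a[3]); sw <- sin(a[3])
  Rd <- rbind(c(1, 0, 0), c(0, cd, -sd), c(0, sd, cd))   # about slice axis
  Rh <- rbind(c(ch, 0, sh), c(0, 1, 0), c(-sh, 0, ch))   # about row axis
  Rw <- rbind(c(cw, -sw, 0), c(sw, cw, 0), c(0, 0, 1))   # about col axis
  Rd %*% Rh %*% Rw
}

#' Apply a rigid transform to a volume or mask
#'
#' Resamples \code{vol} so that output voxel at physical position \eqn{p}
#' (about the grid centre) takes the input value at \eqn{R p + t}, where
#' \eqn{R} is the rotation built from the three angles (degrees, about
#' the slice/row/column axes) and \eqn{t} the translation in mm.  Masks
#' use nearest-neighbour interpolation.
#'
#' @param vol a \code{\linkS4class{CTVolume}} or
#'   \code{\linkS4class{LabelMask}}.
#' @param par numeric(6): three rotations (degrees) then three
#'   translations (mm).
#' @param outDims,outSpacing optional output grid (defaults to the input
#'   grid).
#' @param fill fill value outside the field of view.
#' @return The transformed object.
#' @export
applyRigidTransform <- function(vol, par, outDims = NULL,
                                outSpacing = NULL, fill = NULL) {
  isMask <- is(vol, "LabelMask")
  x <- volData(vol)
  sp <- voxelSpacing(vol)
  if (is.null(outDims)) outDims <- dim(x)
  if (is.null(outSpacing)) outSpacing <- sp
  if (is.null(fill)) fill <- if (isMask) 0 else min(x)
  out <- cpp_resample_affine(as.double(x), dim(x), sp, rigid_matrix(par),
                             par[4:6], as.integer(outDims),
                             as.numeric(outSpacing), nearest = isMask,
                             fill = fill)
  out <- array(out, outDims)
  if (isMask) labelMask(array(as.integer(round(out)), outDims),
                        outSpacing)
  else ctVolume(out, outSpacing, normalised = isNormalised(vol))
}

mutual_information <- function(a, b, nbins = 32L) {
  h <- cpp_joint_hist(as.double(a), as.double(b), nbins, 0, 1)
  p <- h / sum(h)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
}

#' Rigidly co-register two CT volumes
#'
#' Finds the 6-parameter rigid transform (3 rotations, 3 translations)
#' that maximises the mutual information between \code{fixed} and the
#' transformed \code{moving} volume, using a 3-level multi-resolution
#' pyramid and Nelder-Mead optimisation, then resamples \code{moving}
#' onto the grid of \code{fixed}.  Both volumes must be normalised to
#' \eqn{[0, 1]} first.
#'
#' @param fixed,moving normalised \code{\linkS4class{CTVolume}} objects
#'   with overlapping fields of view.
#' @param nbins number of intensity bins for the joint histogram.
#' @param levels pyramid levels, coarse to fine: a list of per-axis
#'   spacing multipliers (the slice axis is already coarse on abdominal
#'   CT and is downsampled less than the in-plane axes).
#' @param maxit Nelder-Mead iteration cap per level.
#' @return A list with \code{transform} (numeric(6)), \code{moving} (the
#'   moving volume resampled onto the fixed grid), and \code{metric}
#'   (final mutual information).
#' @export
rigidRegister <- function(fixed, moving, nbins = 32L,
                          levels = list(c(2, 4, 4), c(1, 2, 2),
                                        c(1, 1, 1)),
                          maxit = c(400, 300, 300)) {
  if (!isNormalised(fixed) || !isNormalised(moving))
    stop("both volumes must be normalised before registration")
  # light Gaussian smoothing (~1.2 mm in plane) for the optimisation
  # metric: it removes spurious local optima produced by noise and thin
  # structures; the final polish below uses the raw metric for
  # sub-voxel precision
  smooth_vol <- function(v) {
    sg <- 1.2 / voxelSpacing(v)   # isotropic in mm: commutes with
                                  # rotations, so the optimum is unbiased
    ctVolume(array(cpp_gauss_smooth(volData(v), dim(volData(v)), sg),
                   dim(volData(v))), voxelSpacing(v), normalised = FALSE)
  }
  fixedS <- smooth_vol(fixed)
  movingS <- smooth_vol(moving)
  par <- numeric(6)
  negmi_raw <- NULL
  negmi <- NULL
  for (i in seq_along(levels)) {
    f <- levels[[i]]
    if (any(f > 1)) {
      sp <- voxelSpacing(fixed) * f
      fx <- resampleVolume(fixedS, sp)
      mv <- resampleVolume(movingS, sp)
    } else {
      fx <- fixedS; mv <- movingS
    }
    fa <- volData(fx)
    negmi <- function(p) {
      tr <- cpp_resample_affine(as.double(volData(mv)), dim(volData(mv)),
                                voxelSpacing(mv), rigid_matrix(p),
                                p[4:6], dim(fa), voxelSpacing(fx),
                                nearest = FALSE, fill = 0)
      -mutual_information(fa, tr, nbins)
    }
    if (i == length(levels)) {
      fr <- volData(fixed); mr <- volData(moving)
      negmi_raw <- function(p) {
        tr <- cpp_resample_affine(as.double(mr), dim(mr),
                                  voxelSpacing(moving), rigid_matrix(p),
                                  p[4:6], dim(fr), voxelSpacing(fixed),
                                  nearest = FALSE, fill = 0)
        -mutual_information(fr, tr, nbins)
      }
    }
    fit_t <- function(p, ps = 8)
      optim(p[4:6], function(tt) negmi(c(p[1:3], tt)),
            method = "Nelder-Mead",
            control = list(maxit = 200, reltol = 1e-10,
                           parscale = rep(ps, 3)))$par
    fit_r <- function(p, ps = 4)
      optim(p[1:3], function(aa) negmi(c(aa, p[4:6])),
            method = "Nelder-Mead",
            control = list(maxit = 200, reltol = 1e-10,
                           parscale = rep(ps, 3)))$par
    if (i == 1L) {
      # robust coarse initialisation: translation-only fit, a rotation
      # grid search, then alternating 3-dof refinements -- far less
      # prone to local optima than a cold 6-dof simplex
      par[4:6] <- fit_t(par)
      ang <- c(-12, -6, 0, 6, 12)
      grid <- as.matrix(expand.grid(a1 = ang, a2 = ang, a3 = ang))
      vals <- apply(grid, 1, function(a) negmi(c(a, par[4:6])))
      par[1:3] <- grid[which.min(vals), ]
    }
    # alternating 3-dof refinements at every level before the 6-dof
    # polish: simplex descent over rotations alone escapes plateaus the
    # full 6-dof simplex tends to stall on
    for (k in 1:2) {
      par[4:6] <- fit_t(par, ps = 8 / 2^(i - 1))
      par[1:3] <- fit_r(par, ps = 4 / 2^(i - 1))
    }
    scales <- c(4, 4, 4, 8, 8, 8) / 2^(i - 1)
    opt <- optim(par, negmi, method = "Nelder-Mead",
                 control = list(maxit = maxit[i], reltol = 1e-10,
                                parscale = scales))
    # refinement restart with a tighter simplex
    opt <- optim(opt$par, negmi, method = "Nelder-Mead",
                 control = list(maxit = maxit[i], reltol = 1e-10,
                                parscale = scales / 8))
    par <- opt$par
    if (i == length(levels)) {
      # coordinate-wise Brent polish: the in-plane rotation valley is
      # much flatter than the translation axes, which stalls a joint
      # simplex; one-dimensional line searches climb it reliably
      # precision polish on the raw (unsmoothed) metric: the smoothed
      # metric locates the basin, but smoothing correlates the noise
      # and can displace the optimum by a fraction of a degree
      for (sweep in 1:3) {
        for (j in 1:6) {
          half <- if (j <= 3) 2 else 1.5
          cur <- negmi_raw(par)
          o1 <- stats::optimize(function(v) {
            p <- par; p[j] <- v; negmi_raw(p)
          }, interval = c(par[j] - half, par[j] + half), tol = 1e-3)
          if (o1$objective < cur) par[j] <- o1$minimum
        }
      }
    }
  }
  final_mi <- -negmi_raw(par)
  ident_mi <- -negmi_raw(numeric(6))
  if (final_mi < ident_mi - 1e-6)
    stop(sprintf(paste0("registration failed to converge: final mutual ",
                        "information %.4f below identity %.4f"),
                 final_mi, ident_mi))
  resampled <- applyRigidTransform(moving, par, outDims = dim(fa),
                                   outSpacing = voxelSpacing(fixed),
                                   fill = 0)
  list(transform = par, moving = resampled, metric = final_mi)
}

#' Load and preprocess a longitudinal CT pair
#'
#' Full preprocessing chain: read both scans, attenuation-clip and
#' normalise, resample to the target spacing, rigidly register the
#' follow-up (moving) onto the baseline (fixed) grid, and carry any masks
#' through the same transforms with nearest-neighbour interpolation.
#'
#' @param baselinePath,followupPath NIfTI paths of the pre- and
#'   post-treatment scans (Hounsfield units).
#' @param baselineMaskPath,followupMaskPath optional NIfTI mask paths.
#' @param targetSpacing numeric(3) target voxel spacing in mm.
#' @param register logical; set \code{FALSE} for pairs already on a
#'   common aligned grid (e.g. synthetic phantoms), in which case the
#'   transform is the identity.
#' @param response,recist optional labels attached to the pair.
#' @return A preprocessed \code{\linkS4class{LongitudinalPair}}.
#' @export
preprocessPair <- function(baselinePath, followupPath,
                           baselineMaskPath = NULL,
                           followupMaskPath = NULL,
                           targetSpacing = c(5, 0.8, 0.8),
                           register = TRUE, response = NA,
                           recist = NA_character_) {
  bl <- resampleVolume(clipAndNormalize(readVolume(baselinePath)),
                       targetSpacing)
  fu <- resampleVolume(clipAndNormalize(readVolume(followupPath)),
                       targetSpacing)
  blm <- if (!is.null(baselineMaskPath))
    resampleVolume(readVolume(baselineMaskPath, mask = TRUE),
                   targetSpacing)
  fum <- if (!is.null(followupMaskPath))
    resampleVolume(readVolume(followupMaskPath, mask = TRUE),
                   targetSpacing)
  par <- numeric(6)
  if (register) {
    reg <- rigidRegister(bl, fu)
    par <- reg$transform
    fu <- reg$moving
    if (!is.null(fum))
      fum <- applyRigidTransform(fum, par, outDims = dim(volData(bl)),
                                 outSpacing = targetSpacing)
  } else if (!identical(dim(volData(bl)), dim(volData(fu)))) {
    stop("register = FALSE requires baseline and follow-up on the same ",
         "grid")
  }
  longitudinalPair(bl, fu, baselineMask = blm, followupMask = fum,
                   response = response, recist = recist, transform = par)
}
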