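#' Paired augmentation configuration
#'
#' Each transform has an independent application probability.  Grey-value
#' transforms (intensity shift, intensity scale, Gaussian noise,
#' Gaussian smoothing, contrast adjustment -- applied in that fixed
#' order, output re-clamped to \eqn{[0, 1]}) are drawn independently per
#' time point; the spatial transforms (per-axis flip, isotropic scale,
#' shear, per-axis rotation) are composed into a single affine matrix
#' shared by baseline and follow-up so the pair stays co-aligned.
#' Ranges are conventional medical-imaging choices and are all exposed
#' here.
#'
#' @param pShift,shiftRange intensity shift probability and range.
#' @param pScale,scaleRange multiplicative intensity scale.
#' @param pNoise,noiseSdMax additive Gaussian noise; sd drawn from
#'   \code{(0, noiseSdMax)}.
#' @param pSmooth,smoothSigmaRange Gaussian smoothing sigma in voxels.
#' @param pContrast,contrastRange contrast factor about the volume mean.
#' @param pFlip flip probability per eligible axis.
#' @param flipAxes logical(3); which axes may flip (slice, row,
#'   column).  Only the left-right (column) axis flips by default:
#'   mirroring the cranio-caudal or ventral-dorsal axes is not an
#'   anatomy-preserving symmetry when lesion classes are defined by
#'   their anatomical site.
#' @param pSpatialScale,spatialScaleRange isotropic spatial scale.
#' @param pShear,shearMax shear; off-diagonal terms drawn from
#'   \code{(-shearMax, shearMax)}.
#' @param pRotation,rotationMaxDeg per-axis rotation probability and
#'   bound in degrees.
#' @return An \code{AugmentConfig} list.
#' @export
augmentConfig <- function(pShift = 0.15, shiftRange = c(-0.1, 0.1),
                          pScale = 0.15, scaleRange = c(0.9, 1.1),
                          pNoise = 0.15, noiseSdMax = 0.05,
                          pSmooth = 0.15,
                          smoothSigmaRange = c(0.5, 1.0),
                          pContrast = 0.15,
                          contrastRange = c(0.75, 1.25), pFlip = 0.5,
                          flipAxes = c(FALSE, FALSE, TRUE),
                          pSpatialScale = 0.15,
                          spatialScaleRange = c(0.85, 1.15),
                          pShear = 0.15, shearMax = 0.1,
                          pRotation = 0.15, rotationMaxDeg = 15) {
  probs <- c(pShift, pScale, pNoise, pSmooth, pContrast, pFlip,
             pSpatialScale, pShear, pRotation)
  stopifnot(all(probs >= 0), all(probs <= 1), noiseSdMax >= 0,
            shearMax >= 0, rotationMaxDeg >= 0)
  structure(list(pShift = pShift, shiftRange = shiftRange,
                 pScale = pScale, scaleRange = scaleRange,
                 pNoise = pNoise, noiseSdMax = noiseSdMax,
                 pSmooth = pSmooth, smoothSigmaRange = smoothSigmaRange,
                 pContrast = pContrast, contrastRange = contrastRange,
                 pFlip = pFlip, flipAxes = as.logical(flipAxes),
                 pSpatialScale = pSpatialScale,
                 spatialScaleRange = spatialScaleRange,
                 pShear = pShear, shearMax = shearMax,
                 pRotation = pRotation,
                 rotationMaxDeg = rotationMaxDeg),
            class = "AugmentConfig")
}

#' Sample a random affine matrix
#'
#' Composes the sampled flip, scale, shear and per-axis rotation draws
#' into one 4x4 homogeneous matrix acting in physical coordinates about
#' the volume centre (translation part zero).  With all application
#' probabilities zero the identity is returned.  Uses R's global RNG;
#' seed with \code{set.seed} for reproducibility.
#'
#' @param config an \code{\link{augmentConfig}}.
#' @return A 4x4 homogeneous transformation matrix.
#' @export
sampleAffine <- function(config) {
  flips <- ifelse(config$flipAxes & runif(3) < config$pFlip, -1, 1)
  scale <- if (runif(1) < config$pSpatialScale)
    runif(1, config$spatialScaleRange[1], config$spatialScaleRange[2])
  else 1
  S <- diag(flips * scale)
  if (runif(1) < config$pShear) {
    sh <- matrix(runif(9, -config$shearMax, config$shearMax), 3, 3)
    diag(sh) <- 0
    S <- (diag(3) + sh) %*% S
  }
  ang <- ifelse(runif(3) < config$pRotation,
                runif(3, -config$rotationMaxDeg, config$rotationMaxDeg),
                0)
  M <- rigid_matrix(c(ang, 0, 0, 0)) %*% S
  out <- diag(4)
  out[1:3, 1:3] <- M
  out
}

#' Apply random grey-value transforms to a volume
#'
#' Applies (with independent probabilities) intensity shift, intensity
#' scale, Gaussian noise, Gaussian smoothing and contrast adjustment, in
#' that fixed order, then clamps to \eqn{[0, 1]}.  Uses R's global RNG.
#'
#' @param vol a normalised \code{\linkS4class{CTVolume}}.
#' @param config an \code{\link{augmentConfig}}.
#' @return The transformed \code{CTVolume}.
#' @export
greyTransform <- function(vol, config) {
  stopifnot(isNormalised(vol))
  x <- volData(vol)
  if (runif(1) < config$pShift)
    x <- x + runif(1, config$shiftRange[1], config$shiftRange[2])
  if (runif(1) < config$pScale)
    x <- x * runif(1, config$scaleRange[1], config$scaleRange[2])
  if (runif(1) < config$pNoise)
    x <- x + array(rnorm(length(x), 0, runif(1, 0, config$noiseSdMax)),
                   dim(x))
  if (runif(1) < config$pSmooth) {
    sg <- runif(1, config$smoothSigmaRange[1],
                config$smoothSigmaRange[2])
    x <- array(cpp_gauss_smooth(as.double(x), dim(x), rep(sg, 3)),
               dim(x))
  }
  if (runif(1) < config$pContrast) {
    f <- runif(1, config$contrastRange[1], config$contrastRange[2])
    x <- mean(x) + (x - mean(x)) * f
  }
  x <- pmin(pmax(x, 0), 1)
  ctVolume(x, voxelSpacing(vol), normalised = TRUE)
}

apply_affine_vol <- function(arr, spacing, M, nearest) {
  out <- cpp_resample_affine(as.double(arr), dim(arr), spacing,
                             M[1:3, 1:3], M[1:3, 4], dim(arr), spacing,
                             nearest = nearest, fill = 0)
  array(out, dim(arr))
}

#' Augment a longitudinal pair
#'
#' One affine matrix is sampled and applied to baseline and follow-up
#' volumes and masks alike (images trilinearly, masks by nearest
#' neighbour, out-of-field voxels filled with 0); grey-value transforms
#' are then drawn independently per time point.  The response label, the
#' RECIST category and the mask label identities are never changed.
#'
#' @param pair a preprocessed, normalised
#'   \code{\linkS4class{LongitudinalPair}}.
#' @param config an \code{\link{augmentConfig}}.
#' @return The augmented \code{LongitudinalPair}.
#' @export
augmentPair <- function(pair, config) {
  M <- sampleAffine(config)
  sp <- voxelSpacing(pair)
  bl <- baseline(pair); fu <- followup(pair)
  blA <- ctVolume(apply_affine_vol(volData(bl), sp, M, FALSE), sp,
                  normalised = isNormalised(bl))
  fuA <- ctVolume(apply_affine_vol(volData(fu), sp, M, FALSE), sp,
                  normalised = isNormalised(fu))
  blM <- baselineMask(pair)
  if (!is.null(blM))
    blM <- labelMask(array(as.integer(round(
      apply_affine_vol(volData(blM), sp, M, TRUE))),
      dim(volData(blM))), sp)
  fuM <- followupMask(pair)
  if (!is.null(fuM))
    fuM <- labelMask(array(as.integer(round(
      apply_affine_vol(volData(fuM), sp, M, TRUE))),
      dim(volData(fuM))), sp)
  blA <- greyTransform(blA, config)
  fuA <- greyTransform(fuA, config)
  longitudinalPair(blA, fuA, baselineMask = blM, followupMask = fuM,
                   response = responseLabel(pair),
                   recist = recistCategory(pair),
                   transform = pair@transform)
}
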