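#' @import methods
#' @importFrom stats optim rnorm runif rbinom quantile sd setNames
#' @importFrom utils write.csv read.csv
#' @useDynLib SiameseCT, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' CTVolume: a 3D CT intensity grid with voxel spacing
#'
#' Holds a scalar 3D grid in axis order (slice, row, column), the voxel
#' spacing in millimetres per axis in the same order, and a flag recording
#' whether the intensities have been attenuation-clipped and rescaled from
#' Hounsfield units to \eqn{[0, 1]}.
#'
#' @slot data 3D numeric array, axis order (slice, row, column).
#' @slot spacing numeric(3), mm per axis (slice, row, column).
#' @slot normalised logical; \code{TRUE} once \code{\link{clipAndNormalize}}
#'   has been applied (all values then lie in \eqn{[0, 1]}).
#' @export
setClass("CTVolume",
  representation(data = "array", spacing = "numeric",
                 normalised = "logical"),
  prototype(normalised = FALSE))

setValidity("CTVolume", function(object) {
  if (length(dim(object@data)) != 3L)
    return("data must be a 3D array")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be three strictly positive values (mm)")
  if (length(object@normalised) != 1L)
    return("normalised must be a single flag")
  if (isTRUE(object@normalised)) {
    rng <- range(object@data)
    if (rng[1] < -1e-8 || rng[2] > 1 + 1e-8)
      return("normalised volume has values outside [0, 1]")
  }
  TRUE
})

#' LabelMask: a 3-class lesion segmentation aligned to a CTVolume
#'
#' Integer grid over \{0 = background, 1 = omental lesion,
#' 2 = pelvic/ovarian lesion\}, sharing grid shape and spacing with the
#' volume it annotates.
#'
#' @slot data 3D array of integer labels in \{0, 1, 2\}.
#' @slot spacing numeric(3), mm per axis (slice, row, column).
#' @export
setClass("LabelMask",
  representation(data = "array", spacing = "numeric"))

setValidity("LabelMask", function(object) {
  if (length(dim(object@data)) != 3L)
    return("data must be a 3D array")
  if (!all(object@data %in% c(0, 1, 2)))
    return("labels must be a subset of {0, 1, 2}")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be three strictly positive values (mm)")
  TRUE
})

setClassUnion("LabelMaskOrNULL", c("LabelMask", "NULL"))

#' LongitudinalPair: co-registered baseline and follow-up CT
#'
#' A pre-treatment (baseline) and post-treatment (follow-up) volume on a
#' common grid, optionally with ground-truth masks, a binary response
#' label (1 = responder, i.e. RECIST complete or partial response) and the
#' RECIST category, plus the rigid transform used to align follow-up onto
#' baseline (6 parameters: 3 rotations in degrees, 3 translations in mm).
#'
#' @slot baseline,followup \code{\linkS4class{CTVolume}} objects.
#' @slot baselineMask,followupMask \code{\linkS4class{LabelMask}} or
#'   \code{NULL}.
#' @slot response integer; 1, 0 or \code{NA}.
#' @slot recist character; one of "CR", "PR", "SD", "PD" or \code{NA}.
#' @slot transform numeric(6) rigid parameters (identity = zeros).
#' @export
setClass("LongitudinalPair",
  representation(baseline = "CTVolume", followup = "CTVolume",
                 baselineMask = "LabelMaskOrNULL",
                 followupMask = "LabelMaskOrNULL",
                 response = "integer", recist = "character",
                 transform = "numeric"),
  prototype(baselineMask = NULL, followupMask = NULL,
            response = NA_integer_, recist = NA_character_,
            transform = numeric(6)))

setValidity("LongitudinalPair", function(object) {
  db <- dim(object@baseline@data); df <- dim(object@followup@data)
  if (!identical(db, df))
    return("baseline and follow-up grids differ")
  if (max(abs(object@baseline@spacing - object@followup@spacing)) > 1e-9)
    return("baseline and follow-up spacing differ")
  for (m in list(object@baselineMask, object@followupMask))
    if (!is.null(m) && !identical(dim(m@data), db))
      return("mask grid does not match the volumes")
  if (!is.na(object@response) && !object@response %in% c(0L, 1L))
    return("response must be 0, 1 or NA")
  if (!is.na(object@recist) &&
      !object@recist %in% c("CR", "PR", "SD", "PD"))
    return("recist must be CR, PR, SD or PD")
  if (!is.na(object@recist) && !is.na(object@response)) {
    want <- as.integer(object@recist %in% c("CR", "PR"))
    if (object@response != want)
      return("response label inconsistent with RECIST category")
  }
  TRUE
})

#' EvalReport: response-prediction and segmentation evaluation summary
#'
#' @slot auc area under the ROC curve.
#' @slot aucCI numeric(2), 95\% bootstrap confidence interval.
#' @slot threshold probability cut-off maximising Youden's index.
#' @slot sensitivity,specificity,ppv,npv operating-point proportions.
#' @slot weightedF1 support-weighted mean F1 across the two classes.
#' @slot dscPerClass matrix with rows "omental", "pelvic_ovarian" and
#'   columns "mean", "sd" of per-scan Dice similarity coefficients.
#' @slot perCase per-case data frame (id, score, label, prediction, DSC).
#' @export
setClass("EvalReport",
  representation(auc = "numeric", aucCI = "numeric", threshold = "numeric",
                 sensitivity = "numeric", specificity = "numeric",
                 ppv = "numeric", npv = "numeric", weightedF1 = "numeric",
                 dscPerClass = "matrix", perCase = "data.frame"))

setValidity("EvalReport", function(object) {
  props <- c(object@sensitivity, object@specificity, object@ppv,
             object@npv, object@weightedF1)
  props <- props[!is.na(props)]
  if (length(props) && (min(props) < 0 || max(props) > 1))
    return("proportions must lie in [0, 1]")
  if (length(object@aucCI) == 2L && !any(is.na(object@aucCI))) {
    if (object@aucCI[1] > object@auc + 1e-9 ||
        object@aucCI[2] < object@auc - 1e-9)
      return("AUC must lie inside its confidence interval")
  }
  TRUE
})
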