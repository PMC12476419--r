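#' Construct a CTVolume
#'
#' @param data 3D numeric array, axis order (slice, row, column).
#' @param spacing numeric(3) voxel spacing in mm (slice, row, column).
#' @param normalised logical; whether values are already in \eqn{[0,1]}.
#' @return A \code{\linkS4class{CTVolume}}.
#' @examples
#' v <- ctVolume(array(0, c(4, 8, 8)), spacing = c(5, 0.8, 0.8))
#' voxelSpacing(v)
#' @export
ctVolume <- function(data, spacing = c(5, 0.8, 0.8), normalised = FALSE) {
  new("CTVolume", data = data, spacing = as.numeric(spacing),
      normalised = normalised)
}

#' Construct a LabelMask
#'
#' @param data 3D array of integer labels in \{0, 1, 2\}.
#' @param spacing numeric(3) voxel spacing in mm (slice, row, column).
#' @return A \code{\linkS4class{LabelMask}}.
#' @export
labelMask <- function(data, spacing = c(5, 0.8, 0.8)) {
  storage.mode(data) <- "integer"
  new("LabelMask", data = data, spacing = as.numeric(spacing))
}

#' Construct a LongitudinalPair
#'
#' @param baseline,followup \code{\linkS4class{CTVolume}} objects on a
#'   common grid.
#' @param baselineMask,followupMask optional
#'   \code{\linkS4class{LabelMask}} objects.
#' @param response binary response label (1 = responder) or \code{NA}.
#' @param recist RECIST 1.1 category ("CR", "PR", "SD", "PD") or \code{NA}.
#' @param transform rigid alignment parameters (3 rotations in degrees,
#'   3 translations in mm); zeros mean identity.
#' @return A \code{\linkS4class{LongitudinalPair}}.
#' @export
longitudinalPair <- function(baseline, followup, baselineMask = NULL,
                             followupMask = NULL, response = NA,
                             recist = NA_character_,
                             transform = numeric(6)) {
  new("LongitudinalPair", baseline = baseline, followup = followup,
      baselineMask = baselineMask, followupMask = followupMask,
      response = as.integer(response), recist = as.character(recist),
      transform = as.numeric(transform))
}

#' @name accessors
#' @title Accessors for SiameseCT data classes
#' @description Slot accessors: \code{volData} returns the raw 3D array of
#'   a volume or mask, \code{voxelSpacing} the mm spacing,
#'   \code{isNormalised} the normalisation flag; \code{baseline},
#'   \code{followup}, \code{baselineMask}, \code{followupMask},
#'   \code{responseLabel} and \code{recistCategory} unpack a
#'   \code{\linkS4class{LongitudinalPair}}.
#' @param x the object.
#' @return The corresponding slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))
#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setGeneric("isNormalised", function(x) standardGeneric("isNormalised"))
#' @rdname accessors
#' @export
setGeneric("baseline", function(x) standardGeneric("baseline"))
#' @rdname accessors
#' @export
setGeneric("followup", function(x) standardGeneric("followup"))
#' @rdname accessors
#' @export
setGeneric("baselineMask", function(x) standardGeneric("baselineMask"))
#' @rdname accessors
#' @export
setGeneric("followupMask", function(x) standardGeneric("followupMask"))
#' @rdname accessors
#' @export
setGeneric("responseLabel", function(x) standardGeneric("responseLabel"))
#' @rdname accessors
#' @export
setGeneric("recistCategory",
           function(x) standardGeneric("recistCategory"))

#' @rdname accessors
setMethod("volData", "CTVolume", function(x) x@data)
#' @rdname accessors
setMethod("volData", "LabelMask", function(x) x@data)
#' @rdname accessors
setMethod("voxelSpacing", "CTVolume", function(x) x@spacing)
#' @rdname accessors
setMethod("voxelSpacing", "LabelMask", function(x) x@spacing)
#' @rdname accessors
setMethod("voxelSpacing", "LongitudinalPair",
          function(x) x@baseline@spacing)
#' @rdname accessors
setMethod("isNormalised", "CTVolume", function(x) x@normalised)
#' @rdname accessors
setMethod("baseline", "LongitudinalPair", function(x) x@baseline)
#' @rdname accessors
setMethod("followup", "LongitudinalPair", function(x) x@followup)
#' @rdname accessors
setMethod("baselineMask", "LongitudinalPair", function(x) x@baselineMask)
#' @rdname accessors
setMethod("followupMask", "LongitudinalPair", function(x) x@followupMask)
#' @rdname accessors
setMethod("responseLabel", "LongitudinalPair", function(x) x@response)
#' @rdname accessors
setMethod("recistCategory", "LongitudinalPair", function(x) x@recist)

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("CTVolume %dx%dx%d voxels, spacing %s mm, %s\n",
              d[1], d[2], d[3],
              paste(format(object@spacing), collapse = " x "),
              if (object@normalised) "normalised [0,1]" else
                "Hounsfield units"))
  cat(sprintf("  intensity range [%.3g, %.3g]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "LabelMask", function(object) {
  d <- dim(object@data)
  tab <- table(factor(object@data, levels = 0:2))
  cat(sprintf("LabelMask %dx%dx%d voxels, spacing %s mm\n", d[1], d[2],
              d[3], paste(format(object@spacing), collapse = " x ")))
  cat(sprintf("  background %d | omental %d | pelvic/ovarian %d voxels\n",
              tab[1], tab[2], tab[3]))
})

setMethod("show", "LongitudinalPair", function(object) {
  d <- dim(object@baseline@data)
  cat(sprintf("LongitudinalPair %dx%dx%d voxels, spacing %s mm\n",
              d[1], d[2], d[3],
              paste(format(object@baseline@spacing), collapse = " x ")))
  cat(sprintf("  masks: %s | response: %s | RECIST: %s\n",
              if (is.null(object@baselineMask)) "absent" else "present",
              ifelse(is.na(object@response), "NA",
                     ifelse(object@response == 1L, "responder",
                            "non-responder")),
              object@recist))
})

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport\n")
  cat(sprintf("  AUC %.3f (95%% CI %.3f-%.3f), threshold %.3f\n",
              object@auc, object@aucCI[1], object@aucCI[2],
              object@threshold))
  cat(sprintf("  sens %.3f | spec %.3f | PPV %.3f | NPV %.3f | wF1 %.3f\n",
              object@sensitivity, object@specificity, object@ppv,
              object@npv, object@weightedF1))
  for (r in rownames(object@dscPerClass))
    cat(sprintf("  DSC %s: %.3f +/- %.3f\n", r,
                object@dscPerClass[r, "mean"],
                object@dscPerClass[r, "sd"]))
})
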