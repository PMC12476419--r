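#' Read a NIfTI scalar volume
#'
#' Reads a 3D NIfTI file into a \code{\linkS4class{CTVolume}} (or a
#' \code{\linkS4class{LabelMask}} when \code{mask = TRUE}).  Axis order is
#' taken as stored, interpreted as (slice, row, column); the voxel spacing
#' is read from the NIfTI header.
#'
#' @param path path to a \code{.nii} or \code{.nii.gz} file.
#' @param mask logical; read as an integer label mask.
#' @param normalised logical; mark the volume as already normalised.
#' @return A \code{CTVolume} or \code{LabelMask}.
#' @export
readVolume <- function(path, mask = FALSE, normalised = FALSE) {
  if (!file.exists(path))
    stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D scalar volume, got ", length(d), " dimensions: ",
         path)
  spacing <- attr(img, "pixdim")
  if (is.null(spacing)) spacing <- RNifti::pixdim(img)
  spacing <- as.numeric(spacing)[seq_len(3)]
  arr <- array(as.numeric(img), dim = d)
  if (mask)
    labelMask(array(as.integer(round(arr)), d), spacing)
  else
    ctVolume(arr, spacing, normalised = normalised)
}

#' Write a volume or mask to NIfTI
#'
#' @param vol a \code{\linkS4class{CTVolume}} or
#'   \code{\linkS4class{LabelMask}}.
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(vol, path) {
  arr <- volData(vol)
  if (is(vol, "LabelMask")) storage.mode(arr) <- "integer"
  img <- RNifti::asNifti(arr)
  img <- RNifti::`pixdim<-`(img, voxelSpacing(vol))
  RNifti::writeNifti(img, path)
  invisible(path)
}
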