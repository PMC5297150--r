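# NIfTI-1 input/output. The stored array order defines (row, column, slice);
# no reorientation to anatomical axes is attempted (denoising is
# orientation-agnostic).

#' Read a 3D volume from a NIfTI-1 file
#'
#' Reads `.nii` / `.nii.gz` via the NIfTI-1 header, taking voxel spacing from
#' `pixdim` and applying the format's scale/intercept as stored. 4D files
#' with a singleton fourth dimension are accepted. Negative stored
#' intensities are rejected: magnitude MR data are nonnegative, so negative
#' values indicate a non-magnitude input (e.g. a phase or difference image)
#' that this model does not describe.
#'
#' @param path Path to a NIfTI-1 file.
#' @return An [image_stack()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("input file does not exist: '%s'", path), call. = FALSE)
  }
  if (dir.exists(path)) {
    stop(sprintf(paste0(
      "'%s' is a directory; pass a NIfTI-1 file (.nii/.nii.gz). ",
      "DICOM series are not read directly: convert to NIfTI first ",
      "(e.g. with dcm2niix)"), path), call. = FALSE)
  }
  img <- RNifti::readNifti(path)
  vals <- as.array(img)
  d <- dim(vals)
  if (length(d) == 4L && d[4] == 1L) {
    vals <- array(vals, d[1:3])
    d <- d[1:3]
  }
  if (length(d) != 3L) {
    stop(sprintf("expected a 3D volume, got %d dimensions", length(d)), call. = FALSE)
  }
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0)) {
    warning("missing or invalid voxel spacing in header; assuming 1 x 1 x 1 mm")
    sp <- c(1, 1, 1)
  }
  if (any(vals < 0)) {
    stop(paste0(
      "volume contains negative intensities; this tool models nonnegative ",
      "magnitude MR data. If this is magnitude data with an offset, remove ",
      "the offset before denoising"), call. = FALSE)
  }
  image_stack(vals, spacing = sp)
}

#' Write a 3D volume to a NIfTI-1 file
#'
#' Writes the stack with its spacing in the header, as double-precision data
#' (lossless round trip). Paths ending in `.gz` are gzip-compressed
#' transparently.
#'
#' @param stack An [image_stack()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  img <- RNifti::asNifti(array(unclass(stack), dim(stack)))
  RNifti::pixdim(img) <- stack_spacing(stack)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}
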