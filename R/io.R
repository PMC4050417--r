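#' Read a 3-D SUV image or mask from a NIfTI-1 file
#'
#' The grid geometry (spacing, origin) is taken from the NIfTI header; values
#' are cast to double. Only scalar 3-D volumes are accepted: 4-D files and
#' files with non-positive spacing are rejected. Images written by
#' \code{\link{write_image}} round-trip exactly.
#'
#' @param path path to a \code{.nii} or \code{.nii.gz} file.
#' @param mask if \code{TRUE}, interpret the volume as a binary mask (values
#'   must be 0/1) and return a \code{binary_mask}.
#' @return An \code{suv_image}, or a \code{binary_mask} when \code{mask=TRUE}.
#' @export
read_image <- function(path, mask = FALSE) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path))
  hdr <- RNifti::niftiHeader(path)
  ndim <- hdr$dim[1]
  # the raw header spacing, before RNifti sanitizes it for display
  sp_raw <- hdr$pixdim[2:(1 + min(ndim, 3))]
  if (any(!is.finite(sp_raw)) || any(sp_raw <= 0))
    stop(sprintf("%s: non-positive voxel spacing in header", path))
  nii <- RNifti::readNifti(path)
  arr <- as.array(nii)
  d <- dim(arr)
  if (length(d) == 4L && d[4] == 1L) {
    arr <- array(arr, d[1:3])
    d <- d[1:3]
  }
  if (length(d) != 3L)
    stop(sprintf("%s: expected a scalar 3-D volume, got %d dimensions",
                 path, length(d)))
  sp <- RNifti::pixdim(nii)[1:3]
  xf <- RNifti::xform(nii)
  org <- as.numeric(xf[1:3, 4])
  geom <- grid_geometry(d, sp, org)
  if (mask) {
    binary_mask(array(arr != 0, d), geom)
  } else {
    storage.mode(arr) <- "double"
    suv_image(arr, geom)
  }
}

#' Write an SUV image or binary mask to a NIfTI-1 file
#'
#' Spacing and origin are preserved in the header (diagonal sform). Masks are
#' stored as 8-bit \{0,1\}; images as 32-bit float.
#'
#' @param img an \code{suv_image} or \code{binary_mask}.
#' @param path output path (\code{.nii} or \code{.nii.gz}); the parent
#'   directory must exist.
#' @return \code{path}, invisibly.
#' @export
write_image <- function(img, path) {
  if (!dir.exists(dirname(path)))
    stop(sprintf("parent directory does not exist: %s", dirname(path)))
  is_mask <- inherits(img, "binary_mask")
  if (!is_mask && !inherits(img, "suv_image"))
    stop("img must be an suv_image or binary_mask")
  g <- img$geometry
  arr <- if (is_mask) array(as.integer(img$values), g$shape) else img$values
  nii <- RNifti::asNifti(arr)
  RNifti::pixdim(nii) <- g$spacing
  m <- rbind(cbind(diag(g$spacing), g$origin), c(0, 0, 0, 1))
  RNifti::qform(nii) <- structure(m, code = 2L)
  RNifti::sform(nii) <- structure(m, code = 2L)
  RNifti::writeNifti(nii, path,
                     datatype = if (is_mask) "uint8" else "float")
  invisible(path)
}
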