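#' SUV image
#'
#' A 3-D scalar voxel grid in body-weight SUV units on a \code{grid_geometry}.
#' Values must be finite and non-negative.
#'
#' @param values numeric 3-D array matching \code{geometry$shape}.
#' @param geometry a \code{grid_geometry}.
#' @return An object of class \code{suv_image} (list with \code{values},
#'   \code{geometry}).
#' @export
suv_image <- function(values, geometry) {
  stopifnot(inherits(geometry, "grid_geometry"))
  values <- as.array(values)
  if (!identical(dim(values), NULL) && length(dim(values)) != 3L)
    stop("values must be a 3-D array")
  if (!identical(as.integer(dim(values)), geometry$shape))
    stop("values dimensions do not match geometry shape")
  storage.mode(values) <- "double"
  if (any(!is.finite(values)))
    stop("SUV values must be finite")
  if (any(values < 0))
    stop("SUV values must be non-negative")
  structure(list(values = values, geometry = geometry), class = "suv_image")
}

#' Binary voxel mask
#'
#' A boolean voxel grid on a \code{grid_geometry}; used for all target
#' volumes (BTV, BITV, CTV, PTV, PTVg) and organ masks.
#'
#' @param values logical (or 0/1 numeric) 3-D array matching the geometry.
#' @param geometry a \code{grid_geometry}.
#' @return An object of class \code{binary_mask}.
#' @export
binary_mask <- function(values, geometry) {
  stopifnot(inherits(geometry, "grid_geometry"))
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("values must be a 3-D array")
  if (!identical(as.integer(dim(values)), geometry$shape))
    stop("values dimensions do not match geometry shape")
  if (is.numeric(values)) {
    if (any(!is.finite(values)) || any(!values %in% c(0, 1)))
      stop("numeric mask values must be 0 or 1")
    values <- array(values != 0, dim = dim(values))
  }
  if (!is.logical(values))
    stop("mask values must be logical or 0/1 numeric")
  if (anyNA(values))
    stop("mask values must not contain NA")
  structure(list(values = values, geometry = geometry), class = "binary_mask")
}

#' @export
print.suv_image <- function(x, ...) {
  cat(sprintf("suv_image: %d x %d x %d, SUV range [%.3g, %.3g]\n",
              x$geometry$shape[1], x$geometry$shape[2], x$geometry$shape[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("binary_mask: %d x %d x %d, %d voxels set (%.3g cc)\n",
              x$geometry$shape[1], x$geometry$shape[2], x$geometry$shape[3],
              sum(x$values), volume_cc(x)))
  invisible(x)
}

#' Mask volume in cubic centimetres
#'
#' Volume by voxel counting: number of set voxels times the voxel volume.
#' No sub-voxel surface correction is applied; this matches how clinical
#' treatment-planning systems report contour volumes on a voxel grid.
#'
#' @param mask a \code{binary_mask}.
#' @return Volume in cc; 0 for an empty mask.
#' @examples
#' g <- grid_geometry(c(10, 10, 10), spacing = c(2, 2, 2))
#' m <- binary_mask(array(TRUE, c(10, 10, 10)), g)
#' volume_cc(m)  # 1000 voxels x 0.008 cc = 8 cc
#' @export
volume_cc <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$values) * voxel_volume_cc(mask$geometry)
}

#' Ordered series of respiratory-gated SUV images
#'
#' All phases share one grid. Phase fractions are the fractions of the
#' breathing cycle covered by each bin and must sum to 1 (equal by default,
#' matching six phases distributed equally over the cycle).
#'
#' @param phases list of \code{suv_image} objects (default length 6).
#' @param fractions numeric vector of phase fractions summing to 1.
#' @return An object of class \code{gated_series}.
#' @export
gated_series <- function(phases, fractions = NULL) {
  if (!length(phases))
    stop("a gated series needs at least one phase")
  if (!all(vapply(phases, inherits, logical(1), "suv_image")))
    stop("all phases must be suv_image objects")
  g <- phases[[1]]$geometry
  for (p in phases[-1]) check_same_geometry(g, p$geometry, "gated phases")
  if (is.null(fractions))
    fractions <- rep(1 / length(phases), length(phases))
  if (length(fractions) != length(phases))
    stop("one phase fraction per phase is required")
  if (abs(sum(fractions) - 1) > 1e-8 || any(fractions <= 0))
    stop("phase fractions must be positive and sum to 1")
  structure(list(phases = phases, fractions = fractions, geometry = g),
            class = "gated_series")
}

#' @export
print.gated_series <- function(x, ...) {
  cat(sprintf("gated_series: %d phases on a %d x %d x %d grid\n",
              length(x$phases),
              x$geometry$shape[1], x$geometry$shape[2], x$geometry$shape[3]))
  invisible(x)
}

#' @export
length.gated_series <- function(x) length(x$phases)

#' Set algebra on binary masks
#'
#' Voxel-wise union, intersection and difference of masks sharing one grid;
#' a geometry mismatch is an error (no resampling).
#'
#' @param a,b \code{binary_mask} objects on the same grid.
#' @return A \code{binary_mask}.
#' @export
mask_union <- function(a, b) {
  check_same_geometry(a$geometry, b$geometry, "masks")
  binary_mask(a$values | b$values, a$geometry)
}

#' @rdname mask_union
#' @export
mask_intersect <- function(a, b) {
  check_same_geometry(a$geometry, b$geometry, "masks")
  binary_mask(a$values & b$values, a$geometry)
}

#' @rdname mask_union
#' @export
mask_diff <- function(a, b) {
  check_same_geometry(a$geometry, b$geometry, "masks")
  binary_mask(a$values & !b$values, a$geometry)
}

#' All-false mask on a grid
#'
#' @param geometry a \code{grid_geometry}.
#' @return An empty \code{binary_mask}.
#' @export
empty_mask <- function(geometry) {
  binary_mask(array(FALSE, geometry$shape), geometry)
}
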