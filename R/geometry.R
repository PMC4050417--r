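#' Voxel-grid geometry
#'
#' Describes a regular 3-D voxel grid: array shape, physical voxel spacing in
#' millimetres, and the world position of the centre of voxel (1,1,1). The
#' third axis (z) is the craniocaudal direction by convention; x and y are
#' in-plane (radial). Voxels are half-open boxes centred on their grid point.
#'
#' @param shape integer vector of length 3, voxels per axis (all >= 1).
#' @param spacing numeric vector of length 3, voxel spacing in mm (all > 0).
#' @param origin numeric vector of length 3, world coordinate (mm) of the
#'   centre of the first voxel.
#' @return An object of class \code{grid_geometry}.
#' @examples
#' g <- grid_geometry(c(64, 64, 40), spacing = c(2, 2, 2))
#' voxel_volume_cc(g)  # 0.008
#' @export
grid_geometry <- function(shape, spacing = c(2, 2, 2), origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(shape) != 3L || length(spacing) != 3L || length(origin) != 3L)
    stop("shape, spacing and origin must each have length 3")
  if (any(!is.finite(shape)) || any(shape < 1L))
    stop("all shape entries must be >= 1")
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("all spacings must be strictly positive")
  if (any(!is.finite(origin)))
    stop("origin must be finite")
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("grid_geometry: %d x %d x %d voxels, spacing %g x %g x %g mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Volume of one voxel in cubic centimetres
#'
#' @param geometry a \code{grid_geometry}.
#' @return Voxel volume in cc (sx*sy*sz / 1000).
#' @export
voxel_volume_cc <- function(geometry) {
  stopifnot(inherits(geometry, "grid_geometry"))
  prod(geometry$spacing) / 1000
}

#' Test whether two geometries describe the same grid
#'
#' @param a,b \code{grid_geometry} objects.
#' @param tol relative tolerance on spacing and origin.
#' @return logical.
#' @export
same_geometry <- function(a, b, tol = 1e-6) {
  stopifnot(inherits(a, "grid_geometry"), inherits(b, "grid_geometry"))
  identical(a$shape, b$shape) &&
    all(abs(a$spacing - b$spacing) <= tol * pmax(1, abs(a$spacing))) &&
    all(abs(a$origin - b$origin) <= tol * pmax(1, abs(a$origin)))
}

# stop() unless a and b share one grid; `what` names the offending argument
check_same_geometry <- function(a, b, what = "images") {
  if (!same_geometry(a, b))
    stop(sprintf("geometry mismatch between %s: grids must be identical (no resampling is performed)",
                 what))
  invisible(TRUE)
}

#' World coordinates (mm) of voxel centres along each axis
#'
#' @param geometry a \code{grid_geometry}.
#' @return list of numeric vectors \code{x}, \code{y}, \code{z}.
#' @export
axis_coords <- function(geometry) {
  stopifnot(inherits(geometry, "grid_geometry"))
  list(x = geometry$origin[1] + (seq_len(geometry$shape[1]) - 1) * geometry$spacing[1],
       y = geometry$origin[2] + (seq_len(geometry$shape[2]) - 1) * geometry$spacing[2],
       z = geometry$origin[3] + (seq_len(geometry$shape[3]) - 1) * geometry$spacing[3])
}

# voxel index triples (N x 3 integer matrix) -> world mm coordinates (N x 3)
voxel_to_world <- function(geometry, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  sweep(sweep(ijk - 1, 2, geometry$spacing, "*"), 2, geometry$origin, "+")
}

# linear indices -> voxel index triples (N x 3 integer matrix), 1-based
linear_to_ijk <- function(geometry, idx) {
  nx <- geometry$shape[1]; ny <- geometry$shape[2]
  idx0 <- idx - 1L
  k <- idx0 %/% (nx * ny)
  r <- idx0 %% (nx * ny)
  cbind(i = r %% nx + 1L, j = r %/% nx + 1L, k = k + 1L)
}

# voxel index triples -> linear indices
ijk_to_linear <- function(geometry, ijk) {
  nx <- geometry$shape[1]; ny <- geometry$shape[2]
  as.integer(ijk[, 1] + (ijk[, 2] - 1L) * nx + (ijk[, 3] - 1L) * nx * ny)
}
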