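#' Margin specification for planning-volume expansion
#'
#' A radial (in-plane x/y) and a craniocaudal (z) margin in millimetres. The
#' expansion kernel is the ellipsoid
#' \{ (dx,dy,dz) : (dx/r)^2 + (dy/r)^2 + (dz/c)^2 <= 1 \} — the
#' distance-isotropic realization of a direction-dependent margin recipe.
#'
#' @param radial_mm in-plane margin in mm (>= 0).
#' @param cc_mm craniocaudal margin in mm (>= 0).
#' @return An object of class \code{margin_spec} with a \code{kind} field
#'   (\code{"isotropic"} when the two margins are equal).
#' @export
margin_spec <- function(radial_mm, cc_mm = radial_mm) {
  if (!is.finite(radial_mm) || !is.finite(cc_mm) || radial_mm < 0 || cc_mm < 0)
    stop("margins must be finite and non-negative")
  structure(list(radial_mm = radial_mm, cc_mm = cc_mm,
                 kind = if (radial_mm == cc_mm) "isotropic" else "anisotropic"),
            class = "margin_spec")
}

#' Expand a mask by a margin
#'
#' Morphological dilation of the mask by the ellipsoidal kernel of the margin
#' spec, computed on the voxel lattice in physical (mm) coordinates, so
#' anisotropic grids are handled without resampling. A voxel is set in the
#' output iff some input voxel centre lies within the (closed) ellipsoid
#' centred on it. The result is always a superset of the input.
#'
#' @param mask a \code{binary_mask}.
#' @param spec a \code{margin_spec}.
#' @return The expanded \code{binary_mask}.
#' @examples
#' g <- grid_geometry(c(20, 20, 20), spacing = c(1, 1, 1))
#' a <- array(FALSE, c(20, 20, 20)); a[10, 10, 10] <- TRUE
#' m <- expand_mask(binary_mask(a, g), margin_spec(5, 10))
#' volume_cc(m)  # ~ 4/3 pi * 5 * 5 * 10 / 1000 = 1.047 cc
#' @export
expand_mask <- function(mask, spec) {
  stopifnot(inherits(mask, "binary_mask"), inherits(spec, "margin_spec"))
  if (spec$radial_mm == 0 && spec$cc_mm == 0) return(mask)
  g <- mask$geometry
  offs <- ellipsoid_offsets(c(spec$radial_mm, spec$radial_mm, spec$cc_mm),
                            g$spacing)
  fg <- which(mask$values)
  if (!length(fg)) return(mask)
  ijk <- linear_to_ijk(g, fg)
  out <- array(FALSE, g$shape)
  nx <- g$shape[1]; ny <- g$shape[2]; nz <- g$shape[3]
  for (o in seq_len(nrow(offs))) {
    ii <- ijk[, 1] + offs[o, 1]
    jj <- ijk[, 2] + offs[o, 2]
    kk <- ijk[, 3] + offs[o, 3]
    ok <- ii >= 1L & ii <= nx & jj >= 1L & jj <= ny & kk >= 1L & kk <= nz
    if (!any(ok)) next
    out[ii[ok] + (jj[ok] - 1L) * nx + (kk[ok] - 1L) * nx * ny] <- TRUE
  }
  binary_mask(out, g)
}

# integer voxel offsets whose mm displacement lies in the closed ellipsoid
# with semi-axes `semi` (mm); axes with a zero semi-axis admit offset 0 only
ellipsoid_offsets <- function(semi, spacing) {
  n <- ifelse(semi > 0, floor(semi / spacing), 0)
  grid <- as.matrix(expand.grid(di = seq(-n[1], n[1]),
                                dj = seq(-n[2], n[2]),
                                dk = seq(-n[3], n[3])))
  mm <- sweep(grid, 2, spacing, "*")
  q <- rep(0, nrow(grid))
  for (a in 1:3) {
    if (semi[a] > 0) q <- q + (mm[, a] / semi[a])^2
    # semi == 0: offsets along that axis are already restricted to 0
  }
  grid <- grid[q <= 1 + 1e-12, , drop = FALSE]
  storage.mode(grid) <- "integer"
  grid
}

#' Gated planning target volume: BITV plus an isotropic 3 mm set-up margin
#'
#' @param bitv a \code{binary_mask} (the BITV).
#' @param margin_mm isotropic margin in mm (default 3).
#' @return The PTVg as a \code{binary_mask}.
#' @export
make_ptvg <- function(bitv, margin_mm = 3) {
  expand_mask(bitv, margin_spec(margin_mm, margin_mm))
}

#' Conventional planning target volume: CTV plus 5 mm radial / 10 mm
#' craniocaudal margins
#'
#' The anisotropic margin accounts for both respiratory tumor motion and
#' set-up uncertainty when no gated imaging informs the internal margin.
#'
#' @param ctv a \code{binary_mask} (the CTV).
#' @param radial_mm in-plane margin (default 5).
#' @param cc_mm craniocaudal margin (default 10).
#' @return The PTV as a \code{binary_mask}.
#' @export
make_ptv <- function(ctv, radial_mm = 5, cc_mm = 10) {
  expand_mask(ctv, margin_spec(radial_mm, cc_mm))
}
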