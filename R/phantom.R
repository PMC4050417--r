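#' Hot-sphere specification for the synthetic phantom
#'
#' @param center_mm world coordinate (mm) of the sphere centre (at rest).
#' @param suv uniform SUV inside the sphere.
#' @param radius_mm sphere radius in mm; alternatively give \code{volume_cc}.
#' @param volume_cc sphere volume in cc (converted to a radius).
#' @return An object of class \code{sphere_spec}.
#' @export
sphere_spec <- function(center_mm, suv, radius_mm = NULL, volume_cc = NULL) {
  if (is.null(radius_mm) == is.null(volume_cc))
    stop("give exactly one of radius_mm or volume_cc")
  if (!is.null(volume_cc)) {
    if (volume_cc <= 0) stop("sphere volume must be positive")
    radius_mm <- (3 * volume_cc * 1000 / (4 * pi))^(1 / 3)
  }
  if (radius_mm <= 0) stop("sphere radius must be positive")
  if (length(center_mm) != 3 || any(!is.finite(center_mm)))
    stop("center_mm must be a finite length-3 coordinate")
  structure(list(center_mm = as.numeric(center_mm), radius_mm = radius_mm,
                 suv = suv),
            class = "sphere_spec")
}

#' Background compartment (ellipsoid or cylinder) of the phantom
#'
#' Compartments are painted in list order with sub-voxel fractional blending;
#' cylinders have their axis along z (craniocaudal).
#'
#' @param type \code{"ellipsoid"} or \code{"cylinder"}.
#' @param center_mm world centre (mm).
#' @param suv uniform SUV of the compartment.
#' @param semiaxes_mm length-3 semi-axes (ellipsoid).
#' @param radius_mm,half_height_mm cylinder radius and half-height.
#' @param name optional name; the compartment named \code{"liver"} defines
#'   the liver mask returned by \code{\link{simulate_gated}}.
#' @return An object of class \code{compartment_spec}.
#' @export
compartment_spec <- function(type = c("ellipsoid", "cylinder"), center_mm, suv,
                             semiaxes_mm = NULL, radius_mm = NULL,
                             half_height_mm = NULL, name = "") {
  type <- match.arg(type)
  if (type == "ellipsoid" &&
      (is.null(semiaxes_mm) || length(semiaxes_mm) != 3 || any(semiaxes_mm <= 0)))
    stop("ellipsoid compartments need positive length-3 semiaxes_mm")
  if (type == "cylinder" &&
      (is.null(radius_mm) || is.null(half_height_mm) ||
       radius_mm <= 0 || half_height_mm <= 0))
    stop("cylinder compartments need positive radius_mm and half_height_mm")
  structure(list(type = type, center_mm = as.numeric(center_mm), suv = suv,
                 semiaxes_mm = semiaxes_mm, radius_mm = radius_mm,
                 half_height_mm = half_height_mm, name = name),
            class = "compartment_spec")
}

#' Gated-PET phantom specification
#'
#' Describes hot spheres in a warm background with craniocaudal sinusoidal
#' respiratory motion, Gaussian PSF blur and optional noise, binned into
#' respiratory phases. Phase images are intra-bin time averages
#' (\code{time_supersample} time points per bin), mirroring the residual
#' intra-gate blur of retrospectively binned PET; set
#' \code{time_supersample = 1} for snapshot phases.
#'
#' @param geometry a \code{grid_geometry}.
#' @param compartments list of \code{compartment_spec} (painted in order).
#' @param spheres list of \code{sphere_spec}.
#' @param ambient_suv SUV outside all compartments (default 0).
#' @param amplitude_mm craniocaudal motion amplitude (peak displacement; the
#'   sphere centre moves by amplitude*cos(2 pi t / period)).
#' @param period_s breathing period in seconds (default 4).
#' @param n_phases number of respiratory bins (default 6).
#' @param psf_fwhm_mm isotropic Gaussian PSF FWHM in mm (default 6,
#'   approximating clinical whole-body PET resolution).
#' @param noise list: \code{list(type="none")},
#'   \code{list(type="gaussian", sigma=...)}, or
#'   \code{list(type="scaled_poisson", scale=...)} where the voxel noise SD
#'   is \code{scale*sqrt(value)} (a Poisson-like surrogate).
#' @param seed integer seed for the noise generator.
#' @param supersample spatial supersampling factor per axis for
#'   rasterization (default 3).
#' @param time_supersample time points averaged per phase bin (default 5).
#' @return An object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(geometry, compartments = list(), spheres = list(),
                         ambient_suv = 0, amplitude_mm = 0, period_s = 4,
                         n_phases = 6, psf_fwhm_mm = 6,
                         noise = list(type = "none"), seed = 1L,
                         supersample = 3L, time_supersample = 5L) {
  stopifnot(inherits(geometry, "grid_geometry"))
  if (!all(vapply(compartments, inherits, logical(1), "compartment_spec")))
    stop("compartments must be compartment_spec objects")
  if (!all(vapply(spheres, inherits, logical(1), "sphere_spec")))
    stop("spheres must be sphere_spec objects")
  if (n_phases < 1) stop("n_phases must be >= 1")
  if (psf_fwhm_mm < 0) stop("psf_fwhm_mm must be >= 0")
  if (amplitude_mm < 0) stop("amplitude_mm must be >= 0")
  if (ambient_suv < 0) stop("ambient_suv must be >= 0")
  if (!is.list(noise) || !noise$type %in% c("none", "gaussian", "scaled_poisson"))
    stop("noise$type must be one of none, gaussian, scaled_poisson")
  co <- axis_coords(geometry)
  lim <- list(lo = c(min(co$x), min(co$y), min(co$z)) - geometry$spacing / 2,
              hi = c(max(co$x), max(co$y), max(co$z)) + geometry$spacing / 2)
  for (s in spheres) {
    reach <- s$radius_mm + c(0, 0, amplitude_mm)
    if (any(s$center_mm - reach < lim$lo) || any(s$center_mm + reach > lim$hi))
      stop("a sphere leaves the grid under its maximal motion excursion")
  }
  structure(list(geometry = geometry, compartments = compartments,
                 spheres = spheres, ambient_suv = ambient_suv,
                 amplitude_mm = amplitude_mm, period_s = period_s,
                 n_phases = as.integer(n_phases), psf_fwhm_mm = psf_fwhm_mm,
                 noise = noise, seed = as.integer(seed),
                 supersample = as.integer(supersample),
                 time_supersample = as.integer(time_supersample)),
            class = "phantom_spec")
}

# sub-voxel centre offsets (in voxel units) for supersampling factor s
subvoxel_offsets <- function(s) (seq_len(s) - 0.5) / s - 0.5

# per-voxel inside fraction of a compartment over the whole grid
rasterize_compartment <- function(geometry, comp, supersample) {
  co <- axis_coords(geometry)
  offs <- subvoxel_offsets(supersample)
  frac <- array(0, geometry$shape)
  for (ox in offs) for (oy in offs) for (oz in offs) {
    x <- co$x + ox * geometry$spacing[1]
    y <- co$y + oy * geometry$spacing[2]
    z <- co$z + oz * geometry$spacing[3]
    if (comp$type == "ellipsoid") {
      qx <- ((x - comp$center_mm[1]) / comp$semiaxes_mm[1])^2
      qy <- ((y - comp$center_mm[2]) / comp$semiaxes_mm[2])^2
      qz <- ((z - comp$center_mm[3]) / comp$semiaxes_mm[3])^2
      inside <- outer(outer(qx, qy, "+"), qz, "+") <= 1
    } else {
      qr <- outer((x - comp$center_mm[1])^2, (y - comp$center_mm[2])^2, "+") <=
        comp$radius_mm^2
      qz <- abs(z - comp$center_mm[3]) <= comp$half_height_mm
      inside <- outer(qr, qz, "&")
    }
    frac <- frac + inside
  }
  frac / supersample^3
}

# paint a sphere (fractional blending) into `field`, bounding-box limited;
# returns the modified field
paint_sphere <- function(field, geometry, sph, center_mm, supersample) {
  co <- axis_coords(geometry)
  pad <- sph$radius_mm + max(geometry$spacing)
  xi <- which(co$x >= center_mm[1] - pad & co$x <= center_mm[1] + pad)
  yi <- which(co$y >= center_mm[2] - pad & co$y <= center_mm[2] + pad)
  zi <- which(co$z >= center_mm[3] - pad & co$z <= center_mm[3] + pad)
  if (!length(xi) || !length(yi) || !length(zi)) return(field)
  offs <- subvoxel_offsets(supersample)
  frac <- array(0, c(length(xi), length(yi), length(zi)))
  for (ox in offs) for (oy in offs) for (oz in offs) {
    dx2 <- (co$x[xi] + ox * geometry$spacing[1] - center_mm[1])^2
    dy2 <- (co$y[yi] + oy * geometry$spacing[2] - center_mm[2])^2
    dz2 <- (co$z[zi] + oz * geometry$spacing[3] - center_mm[3])^2
    frac <- frac + (outer(outer(dx2, dy2, "+"), dz2, "+") <= sph$radius_mm^2)
  }
  frac <- frac / supersample^3
  field[xi, yi, zi] <- field[xi, yi, zi] * (1 - frac) + sph$suv * frac
  field
}

# binary ground-truth mask of a sphere at a given centre (majority fraction)
rasterize_sphere_mask <- function(geometry, sph, center_mm, supersample = 3L) {
  field <- array(0, geometry$shape)
  tmp <- paint_sphere(field, geometry, list(radius_mm = sph$radius_mm, suv = 1),
                      center_mm, supersample)
  binary_mask(tmp >= 0.5, geometry)
}

# separable isotropic Gaussian blur on a 3-D array (zero-padded edges,
# kernel normalized to unit sum so uniform interiors are preserved exactly)
gaussian_blur3d <- function(arr, fwhm_mm, spacing) {
  if (fwhm_mm == 0) return(arr)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  for (axis in 1:3) {
    half <- ceiling(4 * sigma / spacing[axis])
    kern <- stats::dnorm(seq(-half, half) * spacing[axis], sd = sigma)
    kern <- kern / sum(kern)
    arr <- conv_along_axis(arr, kern, axis)
  }
  arr
}

conv_along_axis <- function(arr, kern, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(arr, perm), nrow = d[axis])
  n <- nrow(m)
  half <- (length(kern) - 1L) / 2L
  out <- matrix(0, n, ncol(m))
  for (t in seq_along(kern)) {
    off <- t - 1L - half
    dst <- seq_len(n)
    src <- dst + off
    ok <- src >= 1L & src <= n
    out[dst[ok], ] <- out[dst[ok], ] + kern[t] * m[src[ok], ]
  }
  aperm(array(out, d[perm]), order(perm))
}

# Noise is generated as an iid Gaussian field, smoothed with the PSF kernel
# and renormalized to unit marginal variance: reconstructed PET noise is
# correlated at the reconstruction-kernel scale, not white. The voxel SD is
# then `sigma` (gaussian) or `scale*sqrt(value)` (Poisson-like surrogate).
apply_noise <- function(arr, noise, seed, fwhm_mm, spacing) {
  if (noise$type == "none") return(arr)
  d <- dim(arr)
  field <- with_local_seed(seed, array(stats::rnorm(length(arr)), d))
  if (fwhm_mm > 0) {
    field <- gaussian_blur3d(field, fwhm_mm, spacing)
    sigma_k <- fwhm_mm / (2 * sqrt(2 * log(2)))
    shrink <- 1
    for (axis in 1:3) {
      half <- ceiling(4 * sigma_k / spacing[axis])
      kern <- stats::dnorm(seq(-half, half) * spacing[axis], sd = sigma_k)
      kern <- kern / sum(kern)
      shrink <- shrink * sqrt(sum(kern^2))
    }
    field <- field / shrink
  }
  sd_map <- if (noise$type == "gaussian") noise$sigma
            else noise$scale * sqrt(pmax(arr, 0))
  array(pmax(arr + sd_map * field, 0), dim = d)
}

#' Simulate a respiratory-gated phantom acquisition
#'
#' For each phase bin the moving geometry is rasterized at supersampled time
#' points within the bin and averaged (intra-bin blur), convolved with the
#' isotropic Gaussian PSF, and degraded with the phase-indexed seeded noise
#' generator. Ground-truth sphere masks at the bin-centre positions are
#' returned alongside, with the liver compartment mask.
#'
#' @param spec a \code{phantom_spec}.
#' @return List with \code{series} (a \code{gated_series}),
#'   \code{truth} (list per phase of per-sphere \code{binary_mask}s at the
#'   bin-centre position), \code{liver_mask} (\code{binary_mask} or NULL if
#'   no compartment is named \code{"liver"}), and \code{spec}.
#' @export
simulate_gated <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$geometry
  base <- array(spec$ambient_suv, g$shape)
  liver_mask <- NULL
  for (comp in spec$compartments) {
    frac <- rasterize_compartment(g, comp, spec$supersample)
    base <- base * (1 - frac) + comp$suv * frac
    if (identical(comp$name, "liver"))
      liver_mask <- binary_mask(frac >= 0.5, g)
  }
  phases <- vector("list", spec$n_phases)
  truth <- vector("list", spec$n_phases)
  for (p in seq_len(spec$n_phases)) {
    # bin p is centred on cycle time (p-1)/n, so phase 1 dwells at the
    # end-inspiration extreme of the cosine trajectory
    tt <- (p - 1 + (seq_len(spec$time_supersample) - 0.5) /
             spec$time_supersample - 0.5) / spec$n_phases
    acc <- array(0, g$shape)
    for (t in tt) {
      field <- base
      dz <- spec$amplitude_mm * cos(2 * pi * t)
      for (sph in spec$spheres)
        field <- paint_sphere(field, g, sph,
                              sph$center_mm + c(0, 0, dz), spec$supersample)
      acc <- acc + field
    }
    acc <- acc / length(tt)
    acc <- gaussian_blur3d(acc, spec$psf_fwhm_mm, g$spacing)
    acc <- apply_noise(acc, spec$noise,
                       (spec$seed + p * 9973L) %% .Machine$integer.max,
                       spec$psf_fwhm_mm, g$spacing)
    phases[[p]] <- suv_image(acc, g)
    tc <- (p - 1) / spec$n_phases
    dzc <- spec$amplitude_mm * cos(2 * pi * tc)
    truth[[p]] <- lapply(spec$spheres, function(sph)
      rasterize_sphere_mask(g, sph, sph$center_mm + c(0, 0, dzc),
                            spec$supersample))
  }
  list(series = gated_series(phases), truth = truth,
       liver_mask = liver_mask, spec = spec)
}

#' Time-averaged (non-gated) image from a gated series
#'
#' Phase-fraction-weighted voxel-wise mean of the phases — the motion-blurred
#' image a non-gated acquisition of the same activity distribution yields.
#'
#' @param series a \code{gated_series}.
#' @return An \code{suv_image}.
#' @export
simulate_nongated <- function(series) {
  stopifnot(inherits(series, "gated_series"))
  acc <- array(0, series$geometry$shape)
  for (p in seq_along(series$phases))
    acc <- acc + series$fractions[p] * series$phases[[p]]$values
  suv_image(acc, series$geometry)
}

#' Static hot-sphere-in-cylinder quality-assurance phantom preset
#'
#' One centred hot sphere in a warm cylindrical background, matching the
#' classic fillable-sphere QA phantom: sphere volumes 16, 8 or 4 cc, sphere
#' SUV 2, 4 or 8 with matched warm backgrounds of 1.17, 1.19 and 1.23. The
#' phantom is static by construction; requesting motion is an error.
#'
#' @param sphere_volume_cc one of 16, 8, 4.
#' @param sphere_suv one of 2, 4, 8.
#' @param background_suv warm background SUV; defaults to the matched value
#'   for the chosen sphere SUV (2 -> 1.17, 4 -> 1.19, 8 -> 1.23).
#' @param amplitude_mm must be 0.
#' @param psf_fwhm_mm,noise,seed,geometry passed through to
#'   \code{\link{phantom_spec}}; the default grid is isotropic 2 mm, 96^3.
#' @return A \code{phantom_spec}.
#' @export
jaszczak_preset <- function(sphere_volume_cc, sphere_suv,
                            background_suv = NULL, amplitude_mm = 0,
                            psf_fwhm_mm = 6, noise = list(type = "none"),
                            seed = 1L, geometry = NULL) {
  if (!sphere_volume_cc %in% c(16, 8, 4))
    stop("sphere_volume_cc must be one of 16, 8, 4")
  if (!sphere_suv %in% c(2, 4, 8))
    stop("sphere_suv must be one of 2, 4, 8")
  if (amplitude_mm != 0)
    stop("this QA phantom is static: amplitude_mm must be 0")
  if (is.null(background_suv))
    background_suv <- unname(c(`2` = 1.17, `4` = 1.19,
                               `8` = 1.23)[as.character(sphere_suv)])
  if (is.null(geometry))
    geometry <- grid_geometry(c(96, 96, 96), spacing = c(2, 2, 2))
  center <- geometry$origin + (geometry$shape - 1) * geometry$spacing / 2
  spec <- phantom_spec(
    geometry = geometry,
    compartments = list(
      # the warm background doubles as the reference (liver-like) region,
      # so it is named "liver" and returned as the reference mask
      compartment_spec("cylinder", center, suv = background_suv,
                       radius_mm = 80, half_height_mm = 70,
                       name = "liver")),
    spheres = list(sphere_spec(center, suv = sphere_suv,
                               volume_cc = sphere_volume_cc)),
    amplitude_mm = 0, psf_fwhm_mm = psf_fwhm_mm, noise = noise, seed = seed)
  spec$contrast_ratio <- sphere_suv / background_suv
  spec
}

#' Semi-anthropomorphic torso phantom preset
#'
#' Hot sphere inside a liver-like ellipsoid compartment (warm background SUV
#' 2.97) within a body ellipsoid, with lung and mediastinum compartments.
#' Two configurations mirror the physical torso experiments: a 16 cc sphere
#' at SUV 7.9 and an 8 cc sphere at SUV 5.6. Optional craniocaudal
#' sinusoidal motion.
#'
#' @param config \code{"torso16"} (16 cc, SUV 7.9) or \code{"torso8"}
#'   (8 cc, SUV 5.6).
#' @param background_suv liver-compartment SUV (default 2.97).
#' @param amplitude_mm craniocaudal motion amplitude (default 0).
#' @param period_s breathing period (default 4 s).
#' @param psf_fwhm_mm PSF FWHM (default 6 mm).
#' @param noise noise spec (default scaled-Poisson surrogate with scale
#'   0.05, i.e. SD 0.086 SUV at the liver background after PSF-scale
#'   correlation; chosen so that the healthy-liver ROI SUVmax spread
#'   reproduces the clinically observed protocol regime — usually below 0.1,
#'   occasionally in [0.1, 0.2], never above 0.2).
#' @param seed noise seed.
#' @param geometry grid (default isotropic 2 mm, 96^3).
#' @return A \code{phantom_spec}.
#' @export
torso_preset <- function(config = c("torso16", "torso8"),
                         background_suv = 2.97, amplitude_mm = 0,
                         period_s = 4, psf_fwhm_mm = 6,
                         noise = list(type = "scaled_poisson", scale = 0.05),
                         seed = 1L, geometry = NULL) {
  config <- match.arg(config)
  if (is.null(geometry))
    geometry <- grid_geometry(c(96, 96, 96), spacing = c(2, 2, 2))
  center <- geometry$origin + (geometry$shape - 1) * geometry$spacing / 2
  # lesion sits in one lobe so that healthy liver remains available for ROIs
  sph <- if (config == "torso16")
    sphere_spec(center + c(-30, 0, 0), suv = 7.9, volume_cc = 16)
  else
    sphere_spec(center + c(-30, 0, 0), suv = 5.6, volume_cc = 8)
  ext <- (geometry$shape - 1) * geometry$spacing
  spec <- phantom_spec(
    geometry = geometry,
    compartments = list(
      compartment_spec("ellipsoid", center, suv = 1.0,
                       semiaxes_mm = pmin(ext / 2 - 2, c(92, 80, 90)),
                       name = "body"),
      compartment_spec("ellipsoid", center + c(0, 30, 55), suv = 0.2,
                       semiaxes_mm = c(50, 25, 30), name = "lung"),
      compartment_spec("ellipsoid", center + c(0, -35, 50), suv = 1.4,
                       semiaxes_mm = c(25, 18, 28), name = "mediastinum"),
      compartment_spec("ellipsoid", center, suv = background_suv,
                       semiaxes_mm = c(75, 60, 50), name = "liver")),
    spheres = list(sph),
    amplitude_mm = amplitude_mm, period_s = period_s,
    psf_fwhm_mm = psf_fwhm_mm, noise = noise, seed = seed)
  spec$contrast_ratio <- sph$suv / background_suv
  spec
}

#' Radial SUV profile of a Gaussian-blurred uniform sphere
#'
#' Closed-form profile of a uniform sphere (radius R, amplitude A) on a
#' uniform background b after convolution with an isotropic Gaussian of
#' standard deviation sigma.
#'
#' @param r radial distance(s) from the sphere centre, mm.
#' @param R sphere radius, mm.
#' @param A sphere SUV; \code{b} background SUV (A > b).
#' @param b background SUV.
#' @param sigma Gaussian SD in mm (0 = no blur, step profile).
#' @return SUV value(s) at radius \code{r}.
#' @export
blurred_sphere_profile <- function(r, R, A, b, sigma) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(ifelse(r <= R, A, b))
  erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  h <- numeric(length(r))
  small <- r < 1e-8
  if (any(small))
    h[small] <- erf(R / (sqrt(2) * sigma)) -
      sqrt(2 / pi) * (R / sigma) * exp(-R^2 / (2 * sigma^2))
  rr <- r[!small]
  if (length(rr))
    h[!small] <- 0.5 * (erf((R - rr) / (sqrt(2) * sigma)) +
                        erf((R + rr) / (sqrt(2) * sigma))) -
      sigma / (rr * sqrt(2 * pi)) *
        (exp(-(R - rr)^2 / (2 * sigma^2)) - exp(-(R + rr)^2 / (2 * sigma^2)))
  b + (A - b) * h
}

#' Analytic volume of the supra-threshold region of a blurred sphere
#'
#' For a uniform sphere (radius R, SUV A) on background b blurred with an
#' isotropic Gaussian (SD sigma), finds the radius at which the radial
#' profile crosses the threshold tau and returns the enclosed volume. This
#' is the oracle for threshold segmentation on blurred spheres: as tau
#' approaches the background the iso-surface moves far outside the true
#' sphere (the partial-volume mechanism that inflates threshold-at-background
#' volume measurements), and as tau approaches the blurred peak the volume
#' shrinks below the true one.
#'
#' @param R sphere radius, mm.
#' @param A sphere SUV (> b).
#' @param b background SUV.
#' @param sigma Gaussian SD, mm (>= 0).
#' @param tau threshold; must lie strictly between b and the blurred peak
#'   value, otherwise no iso-surface exists and an error is raised.
#' @return Volume in cc of the region where the profile exceeds tau.
#' @export
analytic_blurred_sphere_volume <- function(R, A, b, sigma, tau) {
  if (A <= b) stop("sphere SUV A must exceed background b")
  if (sigma < 0) stop("sigma must be >= 0")
  peak <- blurred_sphere_profile(0, R, A, b, sigma)
  if (tau <= b || tau >= peak)
    stop(sprintf("tau must lie strictly between background (%.4g) and blurred peak (%.4g): no iso-surface", b, peak))
  if (sigma == 0) return(4 / 3 * pi * R^3 / 1000)
  upper <- R + 10 * sigma + 1
  f <- function(r) blurred_sphere_profile(r, R, A, b, sigma) - tau
  if (f(upper) >= 0) stop("threshold iso-surface extends beyond the search radius")
  rstar <- stats::uniroot(f, c(0, upper), tol = 1e-10)$root
  4 / 3 * pi * rstar^3 / 1000
}
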