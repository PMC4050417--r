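#' Acquisition metadata for SUV conversion
#'
#' @param activity_mbq injected activity in MBq (at injection time).
#' @param weight_kg body weight in kg.
#' @param delay_min injection-to-scan delay in minutes (default 60, the
#'   standard FDG uptake time).
#' @param half_life_min isotope half-life in minutes (default 109.77, F-18).
#' @return An object of class \code{acquisition_info}.
#' @export
acquisition_info <- function(activity_mbq, weight_kg, delay_min = 60,
                             half_life_min = 109.77) {
  vals <- c(activity_mbq, weight_kg, delay_min, half_life_min)
  if (any(!is.finite(vals)))
    stop("acquisition parameters must be finite")
  if (activity_mbq <= 0 || weight_kg <= 0 || half_life_min <= 0)
    stop("activity, weight and half-life must be strictly positive")
  if (delay_min < 0)
    stop("injection-to-scan delay must be non-negative")
  structure(list(activity_mbq = activity_mbq, weight_kg = weight_kg,
                 delay_min = delay_min, half_life_min = half_life_min),
            class = "acquisition_info")
}

#' Read acquisition metadata from a YAML or JSON file
#'
#' Expects keys \code{activity_mbq}, \code{weight_kg} and optionally
#' \code{delay_min}, \code{half_life_min}.
#'
#' @param path path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return An \code{acquisition_info}.
#' @export
read_acquisition_info <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  x <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  do.call(acquisition_info, x[intersect(names(x),
    c("activity_mbq", "weight_kg", "delay_min", "half_life_min"))])
}

#' Convert an activity-concentration image to body-weight SUV
#'
#' SUV(v) = C(v) [Bq/mL] * weight [g] / injected activity decayed to scan
#' start [Bq], with decay factor 2^(-delay / half-life). Body-weight
#' normalization (the clinical default) is the only variant implemented.
#'
#' @param activity an \code{suv_image}-shaped object whose values are
#'   activity concentration in Bq/mL (a plain 3-D array with a
#'   \code{grid_geometry} is also accepted via \code{geometry}).
#' @param acq an \code{acquisition_info}.
#' @param geometry required when \code{activity} is a bare array.
#' @return An \code{suv_image} in SUV units.
#' @examples
#' g <- grid_geometry(c(4, 4, 4))
#' acq <- acquisition_info(activity_mbq = 245, weight_kg = 70, delay_min = 0)
#' suv <- compute_suv_map(array(5000, c(4, 4, 4)), acq, geometry = g)
#' suv$values[1, 1, 1]  # ~1.4286
#' @export
compute_suv_map <- function(activity, acq, geometry = NULL) {
  stopifnot(inherits(acq, "acquisition_info"))
  if (inherits(activity, "suv_image")) {
    geometry <- activity$geometry
    activity <- activity$values
  }
  if (is.null(geometry))
    stop("geometry is required when activity is a bare array")
  decayed_bq <- acq$activity_mbq * 1e6 * 2^(-acq$delay_min / acq$half_life_min)
  suv <- activity * (acq$weight_kg * 1000) / decayed_bq
  suv_image(suv, geometry)
}

#' Sample healthy-liver background ROIs and return their SUVmax
#'
#' Places \code{k} pairwise-disjoint spherical ROIs of the requested volume
#' fully inside the healthy-liver mask, with centres drawn reproducibly from
#' the seed (rejection sampling over mask voxels), and returns the maximum
#' SUV within each ROI. The 20-30 cc ROI volume mirrors the clinical
#' background-measurement protocol.
#'
#' @param img an \code{suv_image}.
#' @param liver_mask a \code{binary_mask} of healthy liver (lesions excluded).
#' @param roi_volume_cc ROI volume in cc, must lie in [20, 30].
#' @param k number of ROIs to place.
#' @param seed integer seed for reproducible placement.
#' @param max_attempts rejection-sampling budget per ROI.
#' @return Numeric vector of length \code{k}: SUVmax per ROI, with the ROI
#'   centres (voxel indices) attached as attribute \code{"centers"}.
#' @export
sample_background_rois <- function(img, liver_mask, roi_volume_cc = 25,
                                   k = 3, seed = 1L, max_attempts = 2000L) {
  stopifnot(inherits(img, "suv_image"), inherits(liver_mask, "binary_mask"))
  check_same_geometry(img$geometry, liver_mask$geometry, "image and liver mask")
  if (roi_volume_cc < 20 || roi_volume_cc > 30)
    stop("roi_volume_cc must lie in [20, 30] cc")
  g <- img$geometry
  r_mm <- (3 * roi_volume_cc * 1000 / (4 * pi))^(1 / 3)
  offs <- sphere_offsets(r_mm, g$spacing)
  cand <- which(liver_mask$values)
  if (!length(cand))
    stop("liver mask is empty")
  cand_ijk <- linear_to_ijk(g, cand)
  centers <- matrix(0L, nrow = 0, ncol = 3)
  suvmax <- numeric(0)
  failed_at <- 0L
  # whole-set restarts: a greedy first placement can block later ROIs even
  # when a joint placement exists
  with_local_seed(seed, {
    for (restart in seq_len(25L)) {
      centers <- matrix(0L, nrow = 0, ncol = 3)
      suvmax <- numeric(0)
      for (roi in seq_len(k)) {
        placed <- FALSE
        for (a in seq_len(max_attempts)) {
          ci <- cand_ijk[sample.int(nrow(cand_ijk), 1L), , drop = FALSE]
          vox <- sweep(offs, 2, as.integer(ci), "+")
          inside <- vox[, 1] >= 1L & vox[, 1] <= g$shape[1] &
                    vox[, 2] >= 1L & vox[, 2] <= g$shape[2] &
                    vox[, 3] >= 1L & vox[, 3] <= g$shape[3]
          if (!all(inside)) next
          lin <- ijk_to_linear(g, vox)
          if (!all(liver_mask$values[lin])) next
          if (nrow(centers)) {
            dmm <- sweep(centers, 2, as.integer(ci))
            dmm <- sweep(dmm, 2, g$spacing, "*")
            if (any(sqrt(rowSums(dmm^2)) < 2 * r_mm)) next
          }
          centers <- rbind(centers, as.integer(ci))
          suvmax <- c(suvmax, max(img$values[lin]))
          placed <- TRUE
          break
        }
        if (!placed) { failed_at <- roi; break }
      }
      if (length(suvmax) == k) break
    }
  })
  if (length(suvmax) < k)
    stop(sprintf(paste0("could not place background ROI %d of %d: ",
                        "healthy-liver mask cannot hold another disjoint ",
                        "%.1f cc sphere"), failed_at, k, roi_volume_cc))
  attr(suvmax, "centers") <- centers
  suvmax
}

# voxel offsets (N x 3 int matrix) whose centre lies within r_mm of origin
sphere_offsets <- function(r_mm, spacing) {
  n <- floor(r_mm / spacing)
  dx <- seq(-n[1], n[1]); dy <- seq(-n[2], n[2]); dz <- seq(-n[3], n[3])
  grid <- as.matrix(expand.grid(dx = dx, dy = dy, dz = dz))
  d2 <- (grid[, 1] * spacing[1])^2 + (grid[, 2] * spacing[2])^2 +
        (grid[, 3] * spacing[3])^2
  grid <- grid[d2 <= r_mm^2, , drop = FALSE]
  storage.mode(grid) <- "integer"
  grid
}

# run expr with a temporary RNG state seeded from `seed`
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

#' Individualized segmentation threshold from background ROI SUVmax values
#'
#' Implements the healthy-liver repetition protocol: with three initial ROI
#' SUVmax values, if the maximum pairwise difference is below 0.1 the
#' threshold is computed from those three; if it lies in [0.1, 0.2] two more
#' measurements are requested from \code{more_provider} and the threshold is
#' computed from all five; a spread above 0.2 (among the first three, or
#' among all five) is a protocol failure. The threshold is the arithmetic
#' mean of the retained values.
#'
#' @param roi_suvmax numeric vector of exactly 3 initial ROI SUVmax values.
#' @param more_provider function of one argument (how many more values are
#'   needed, always 2) returning that many additional ROI SUVmax values.
#'   Required only when the initial spread falls in [0.1, 0.2].
#' @return An object of class \code{background_estimate} with fields
#'   \code{roi_suvmax}, \code{spread}, \code{threshold}, \code{n_rois}.
#' @examples
#' background_threshold(c(5.00, 5.05, 5.02))$threshold  # mean of 3
#' @export
background_threshold <- function(roi_suvmax, more_provider = NULL) {
  if (length(roi_suvmax) != 3L)
    stop("exactly 3 initial ROI SUVmax values are required")
  if (any(!is.finite(roi_suvmax)) || any(roi_suvmax < 0))
    stop("ROI SUVmax values must be finite and non-negative")
  spread3 <- max(roi_suvmax) - min(roi_suvmax)
  if (spread3 > 0.2)
    stop(sprintf(paste0("background protocol failure: SUVmax spread %.3f ",
                        "exceeds 0.2 among the first three ROIs"), spread3))
  if (spread3 < 0.1) {
    vals <- roi_suvmax
  } else {
    if (is.null(more_provider))
      stop("initial ROI spread in [0.1, 0.2]: two additional measurements are required but no provider was given")
    extra <- as.numeric(more_provider(2L))
    if (length(extra) != 2L || any(!is.finite(extra)))
      stop("more_provider must return exactly 2 finite values")
    vals <- c(roi_suvmax, extra)
    spread5 <- max(vals) - min(vals)
    if (spread5 > 0.2)
      stop(sprintf(paste0("background protocol failure: SUVmax spread %.3f ",
                          "exceeds 0.2 among the five ROIs"), spread5))
  }
  structure(list(roi_suvmax = vals,
                 spread = max(vals) - min(vals),
                 threshold = mean(vals),
                 n_rois = length(vals)),
            class = "background_estimate")
}

#' @export
print.background_estimate <- function(x, ...) {
  cat(sprintf("background_estimate: threshold SUV %.4g from %d ROIs (spread %.3g)\n",
              x$threshold, x$n_rois, x$spread))
  invisible(x)
}
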