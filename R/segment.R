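#' Threshold segmentation
#'
#' Voxels with SUV strictly greater than the threshold are tumor: the
#' individualized threshold is the healthy-liver background SUVmax, and a
#' value above it is considered part of the lesion.
#'
#' @param img an \code{suv_image}.
#' @param tau segmentation threshold in SUV units, > 0.
#' @return A \code{binary_mask}.
#' @export
threshold_segment <- function(img, tau) {
  stopifnot(inherits(img, "suv_image"))
  if (!is.finite(tau) || tau <= 0)
    stop("threshold tau must be a positive finite SUV value")
  binary_mask(img$values > tau, img$geometry)
}

#' Label lesions as 26-connected components
#'
#' Connected components of the mask under 26-connectivity (faces, edges and
#' corners); components smaller than \code{min_volume_cc} are discarded as
#' noise specks. Labels are consecutive positive integers in order of first
#' voxel occurrence (column-major), which makes labeling deterministic.
#'
#' @param mask a \code{binary_mask}.
#' @param min_volume_cc minimum component volume kept, in cc (default 0.1).
#' @param img optional \code{suv_image} on the same grid; when given, each
#'   lesion's SUVmax is recorded.
#' @return An object of class \code{lesion_set}: list with \code{labels}
#'   (integer array, 0 = background), \code{n}, and data frame \code{stats}
#'   (label, n_voxels, volume_cc, centroid x/y/z in mm, suvmax).
#' @export
label_lesions <- function(mask, min_volume_cc = 0.1, img = NULL) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!is.null(img))
    check_same_geometry(mask$geometry, img$geometry, "mask and image")
  g <- mask$geometry
  lab <- connected_components_26(mask$values)
  labels <- array(lab$labels, g$shape)
  vox_cc <- voxel_volume_cc(g)
  keep <- which(lab$sizes * vox_cc >= min_volume_cc)
  # renumber surviving components consecutively, preserving order
  remap <- integer(length(lab$sizes))
  remap[keep] <- seq_along(keep)
  nz <- labels > 0L
  labels[nz] <- remap[labels[nz]]
  n <- length(keep)
  stats <- data.frame(label = integer(0), n_voxels = integer(0),
                      volume_cc = numeric(0), x_mm = numeric(0),
                      y_mm = numeric(0), z_mm = numeric(0),
                      suvmax = numeric(0))
  if (n > 0) {
    idx <- which(labels > 0L)
    lb <- labels[idx]
    ijk <- linear_to_ijk(g, idx)
    mm <- voxel_to_world(g, ijk)
    sizes <- tabulate(lb, nbins = n)
    stats <- data.frame(
      label = seq_len(n),
      n_voxels = sizes,
      volume_cc = sizes * vox_cc,
      x_mm = as.numeric(tapply(mm[, 1], lb, mean)),
      y_mm = as.numeric(tapply(mm[, 2], lb, mean)),
      z_mm = as.numeric(tapply(mm[, 3], lb, mean)),
      suvmax = if (is.null(img)) NA_real_
               else as.numeric(tapply(img$values[idx], lb, max)))
  }
  structure(list(labels = labels, n = n, stats = stats, geometry = g),
            class = "lesion_set")
}

#' @export
print.lesion_set <- function(x, ...) {
  cat(sprintf("lesion_set: %d lesion(s)\n", x$n))
  if (x$n) print(x$stats, row.names = FALSE)
  invisible(x)
}

# 26-connectivity components of a logical 3-D array via union-find.
# Returns list(labels = integer vector (0 background), sizes per label).
connected_components_26 <- function(vals) {
  d <- dim(vals)
  fg <- which(vals)
  nfg <- length(fg)
  labels <- integer(length(vals))
  if (!nfg) return(list(labels = labels, sizes = integer(0)))
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  lookup <- integer(length(vals))
  lookup[fg] <- seq_len(nfg)
  idx0 <- fg - 1L
  i <- idx0 %% nx
  j <- (idx0 %/% nx) %% ny
  k <- idx0 %/% (nx * ny)
  parent <- seq_len(nfg)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  # half neighborhood: 13 of the 26 offsets (the rest are covered symmetrically)
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & (offs[, 2] > 0 |
            (offs[, 2] == 0 & offs[, 1] > 0))), , drop = FALSE]
  for (o in seq_len(nrow(offs))) {
    ii <- i + offs[o, 1]; jj <- j + offs[o, 2]; kk <- k + offs[o, 3]
    ok <- ii >= 0L & ii < nx & jj >= 0L & jj < ny & kk >= 0L & kk < nz
    if (!any(ok)) next
    nb <- lookup[(ii[ok] + jj[ok] * nx + kk[ok] * nx * ny) + 1L]
    src <- which(ok)[nb > 0L]
    nb <- nb[nb > 0L]
    for (e in seq_along(nb)) {
      ra <- find(src[e]); rb <- find(nb[e])
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots <- vapply(seq_len(nfg), find, integer(1))
  uroots <- unique(roots)          # order of first occurrence = column-major
  comp <- match(roots, uroots)
  labels[fg] <- comp
  list(labels = labels, sizes = tabulate(comp, nbins = length(uroots)))
}

#' Match lesions across gated phases
#'
#' Greedy correspondence between per-phase lesion sets: phase lesions are
#' assigned to an existing track by maximal voxel overlap with the track's
#' accumulated mask, falling back to the nearest track centroid within a
#' capture radius; anything still unmatched starts a new lesion id. A lesion
#' may be absent from phases where it fell below threshold (the mechanism by
#' which small moving lesions vanish from some bins); absence is recorded
#' explicitly as NA.
#'
#' @param lesion_sets list of \code{lesion_set}, one per phase, on one grid.
#' @param capture_radius_mm centroid fallback radius in mm (default 15).
#' @return An object of class \code{lesion_correspondence}: list with
#'   \code{phase_label} (matrix, lesions x phases; NA = absent) and the input
#'   \code{lesion_sets}.
#' @export
match_lesions <- function(lesion_sets, capture_radius_mm = 15) {
  stopifnot(length(lesion_sets) >= 1,
            all(vapply(lesion_sets, inherits, logical(1), "lesion_set")))
  g <- lesion_sets[[1]]$geometry
  for (ls in lesion_sets[-1]) check_same_geometry(g, ls$geometry, "lesion sets")
  n_phase <- length(lesion_sets)
  tracks <- list()   # each: list(mask_idx = linear indices, centroid = mm)
  assign_mat <- matrix(NA_integer_, nrow = 0, ncol = n_phase)
  for (p in seq_len(n_phase)) {
    ls <- lesion_sets[[p]]
    if (ls$n == 0) next
    lab_idx <- lapply(seq_len(ls$n), function(l) which(ls$labels == l))
    cents <- as.matrix(ls$stats[, c("x_mm", "y_mm", "z_mm")])
    unassigned <- seq_len(ls$n)
    if (length(tracks)) {
      # overlap pass, greedy on descending overlap
      ov <- matrix(0L, nrow = length(tracks), ncol = ls$n)
      for (t in seq_along(tracks))
        for (l in unassigned)
          ov[t, l] <- length(intersect(tracks[[t]]$mask_idx, lab_idx[[l]]))
      taken_tracks <- integer(0)
      repeat {
        if (!length(unassigned) || max(ov) == 0L) break
        best <- which(ov == max(ov), arr.ind = TRUE)[1, ]
        t <- best[1]; l <- best[2]
        assign_mat[t, p] <- l
        tracks[[t]]$mask_idx <- union(tracks[[t]]$mask_idx, lab_idx[[l]])
        tracks[[t]]$centroid <- cents[l, ]
        taken_tracks <- c(taken_tracks, t)
        unassigned <- setdiff(unassigned, l)
        ov[t, ] <- 0L; ov[, l] <- 0L
      }
      # centroid fallback for the rest
      if (length(unassigned)) {
        open_tracks <- setdiff(seq_along(tracks), taken_tracks)
        for (l in unassigned[order(unassigned)]) {
          if (!length(open_tracks)) break
          dd <- vapply(open_tracks, function(t)
            sqrt(sum((tracks[[t]]$centroid - cents[l, ])^2)), numeric(1))
          if (min(dd) <= capture_radius_mm) {
            t <- open_tracks[which.min(dd)]
            assign_mat[t, p] <- l
            tracks[[t]]$mask_idx <- union(tracks[[t]]$mask_idx, lab_idx[[l]])
            tracks[[t]]$centroid <- cents[l, ]
            open_tracks <- setdiff(open_tracks, t)
            unassigned <- setdiff(unassigned, l)
          }
        }
      }
    }
    # new tracks for anything left
    for (l in unassigned) {
      tracks[[length(tracks) + 1L]] <-
        list(mask_idx = lab_idx[[l]], centroid = cents[l, ])
      row <- rep(NA_integer_, n_phase)
      row[p] <- l
      assign_mat <- rbind(assign_mat, row)
    }
  }
  rownames(assign_mat) <- NULL
  structure(list(phase_label = assign_mat, lesion_sets = lesion_sets,
                 geometry = g),
            class = "lesion_correspondence")
}

#' @export
print.lesion_correspondence <- function(x, ...) {
  cat(sprintf("lesion_correspondence: %d lesion(s) across %d phase(s)\n",
              nrow(x$phase_label), ncol(x$phase_label)))
  invisible(x)
}

#' Build the biological internal target volume (BITV) for one lesion
#'
#' Voxel-wise union of the lesion's per-phase masks over all phases where the
#' lesion is present. Merging the six gated-phase volumes this way captures
#' the full respiratory excursion of the lesion.
#'
#' @param correspondence a \code{lesion_correspondence}.
#' @param lesion_id row index of the lesion in the correspondence.
#' @return A \code{binary_mask}.
#' @export
build_bitv <- function(correspondence, lesion_id) {
  stopifnot(inherits(correspondence, "lesion_correspondence"))
  m <- correspondence$phase_label
  if (!(lesion_id %in% seq_len(nrow(m))))
    stop(sprintf("unknown lesion id %s (have %d lesions)",
                 as.character(lesion_id), nrow(m)))
  g <- correspondence$geometry
  out <- array(FALSE, g$shape)
  for (p in seq_len(ncol(m))) {
    l <- m[lesion_id, p]
    if (!is.na(l))
      out <- out | (correspondence$lesion_sets[[p]]$labels == l)
  }
  binary_mask(out, g)
}

#' Semi-automatic BTV from a non-gated exam
#'
#' Threshold segmentation followed by selection of the connected component
#' containing the seed point (or the component whose centroid is nearest to
#' the seed, within the capture radius). When no component is found near the
#' seed the result is an empty mask flagged with attribute
#' \code{no_lesion_found = TRUE} and a warning — the situation in which a
#' lesion visible on gated phases is invisible on the motion-blurred
#' non-gated image.
#'
#' @param img the non-gated \code{suv_image}.
#' @param tau segmentation threshold (SUV).
#' @param seed_mm numeric length-3 world coordinate (mm) of the seed point.
#' @param capture_radius_mm capture radius for the nearest-component
#'   fallback (default 15 mm).
#' @param min_volume_cc minimum component volume (default 0.1 cc).
#' @return A \code{binary_mask} (possibly empty, see Details).
#' @export
nongated_btv <- function(img, tau, seed_mm, capture_radius_mm = 15,
                         min_volume_cc = 0.1) {
  stopifnot(inherits(img, "suv_image"), length(seed_mm) == 3)
  g <- img$geometry
  co <- axis_coords(g)
  if (seed_mm[1] < min(co$x) - g$spacing[1] / 2 ||
      seed_mm[1] > max(co$x) + g$spacing[1] / 2 ||
      seed_mm[2] < min(co$y) - g$spacing[2] / 2 ||
      seed_mm[2] > max(co$y) + g$spacing[2] / 2 ||
      seed_mm[3] < min(co$z) - g$spacing[3] / 2 ||
      seed_mm[3] > max(co$z) + g$spacing[3] / 2)
    stop("seed point lies outside the image")
  ls <- label_lesions(threshold_segment(img, tau), min_volume_cc)
  if (ls$n > 0) {
    sv <- pmin(pmax(round((seed_mm - g$origin) / g$spacing) + 1, 1), g$shape)
    seed_label <- ls$labels[sv[1], sv[2], sv[3]]
    if (seed_label > 0L)
      return(binary_mask(ls$labels == seed_label, g))
    cents <- as.matrix(ls$stats[, c("x_mm", "y_mm", "z_mm")])
    dd <- sqrt(rowSums(sweep(cents, 2, seed_mm)^2))
    if (min(dd) <= capture_radius_mm)
      return(binary_mask(ls$labels == ls$stats$label[which.min(dd)], g))
  }
  warning("no supra-threshold lesion within the capture radius of the seed; returning an empty mask")
  out <- empty_mask(g)
  attr(out, "no_lesion_found") <- TRUE
  out
}
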