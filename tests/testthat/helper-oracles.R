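# Independent brute-force oracles and shared fixtures for the test suite.
# Oracles deliberately use the slowest, most direct formulation available so
# they share no code path with the implementation they check.

# cache for expensive simulations shared across test files (one R process)
.sim_cache <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (!exists(name, envir = .sim_cache))
    assign(name, force(expr), envir = .sim_cache)
  get(name, envir = .sim_cache)
}

small_geometry <- function(n = 16, spacing = 2) {
  grid_geometry(rep(n, 3), spacing = rep(spacing, 3))
}

# rasterized sphere mask by direct voxel-centre test (no supersampling)
sphere_mask_centres <- function(geometry, center_mm, radius_mm) {
  co <- axis_coords(geometry)
  d2 <- outer(outer((co$x - center_mm[1])^2, (co$y - center_mm[2])^2, "+"),
              (co$z - center_mm[3])^2, "+")
  binary_mask(d2 <= radius_mm^2, geometry)
}

# brute-force Minkowski dilation: voxel set iff some input voxel centre lies
# within the closed ellipsoid (semi-axes in mm) centred on it
brute_dilate <- function(mask, semi_mm) {
  g <- mask$geometry
  fg <- which(mask$values)
  out <- array(FALSE, g$shape)
  if (!length(fg)) return(binary_mask(out, g))
  fg_ijk <- linear_to_ijk_oracle(g$shape, fg)
  all_ijk <- linear_to_ijk_oracle(g$shape, seq_len(prod(g$shape)))
  for (v in seq_len(nrow(all_ijk))) {
    dv <- sweep(fg_ijk, 2, all_ijk[v, ])
    mm <- sweep(dv, 2, g$spacing, "*")
    q <- rep(0, nrow(mm))
    for (a in 1:3) {
      if (semi_mm[a] > 0) q <- q + (mm[, a] / semi_mm[a])^2
      else q <- q + ifelse(mm[, a] == 0, 0, Inf)
    }
    if (any(q <= 1 + 1e-12)) out[v] <- TRUE
  }
  binary_mask(out, g)
}

linear_to_ijk_oracle <- function(shape, idx) {
  idx0 <- idx - 1L
  cbind(idx0 %% shape[1] + 1L,
        (idx0 %/% shape[1]) %% shape[2] + 1L,
        idx0 %/% (shape[1] * shape[2]) + 1L)
}

# brute-force connected components (26-connectivity) by BFS over voxels
brute_components <- function(mask) {
  g <- mask$geometry
  vals <- mask$values
  d <- dim(vals)
  lab <- array(0L, d)
  cur <- 0L
  for (idx in which(vals)) {
    if (lab[idx] > 0L) next
    cur <- cur + 1L
    queue <- idx
    lab[idx] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      ijk <- linear_to_ijk_oracle(d, v)
      for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
        if (di == 0 && dj == 0 && dk == 0) next
        ii <- ijk[1] + di; jj <- ijk[2] + dj; kk <- ijk[3] + dk
        if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3])
          next
        w <- ii + (jj - 1L) * d[1] + (kk - 1L) * d[1] * d[2]
        if (vals[w] && lab[w] == 0L) {
          lab[w] <- cur
          queue <- c(queue, w)
        }
      }
    }
  }
  lab
}

# exact two-tailed signed-rank p by literal enumeration of all 2^n sign
# assignments (mid-ranks for ties); independent of the DP implementation
enumerate_wilcoxon_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (!n) return(1)
  r <- rank(abs(d))
  W <- min(sum(r[d > 0]), sum(r[d < 0]))
  count <- 0L
  for (bits in 0:(2^n - 1)) {
    signs <- as.logical(bitwAnd(bits, 2^(seq_len(n) - 1)))
    if (sum(r[signs]) <= W + 1e-9) count <- count + 1L
  }
  min(1, 2 * count / 2^n)
}

# numeric radial-integration profile of a Gaussian-blurred uniform sphere:
# 1-D integral of the spherically symmetric convolution kernel
numeric_blurred_profile <- function(r, R, A, b, sigma) {
  f <- function(s, r) {
    s * (exp(-(r - s)^2 / (2 * sigma^2)) - exp(-(r + s)^2 / (2 * sigma^2)))
  }
  h <- vapply(r, function(ri) {
    if (ri < 1e-9) ri <- 1e-9
    stats::integrate(f, 0, R, r = ri, rel.tol = 1e-10)$value /
      (ri * sigma * sqrt(2 * pi))
  }, numeric(1))
  b + (A - b) * h
}

# a shared moving-lesion phantom on a compact grid: warm liver-like ellipsoid
# containing one 10 mm sphere, blur 6 mm, no noise
ladder_spec <- function(amplitude_mm) {
  g <- grid_geometry(c(48, 48, 64), spacing = c(2, 2, 2))
  center <- g$origin + (g$shape - 1) * g$spacing / 2
  phantom_spec(
    geometry = g,
    compartments = list(
      compartment_spec("ellipsoid", center, suv = 2.97,
                       semiaxes_mm = c(42, 42, 58), name = "liver")),
    spheres = list(sphere_spec(center, suv = 7.9, radius_mm = 10)),
    amplitude_mm = amplitude_mm, psf_fwhm_mm = 6,
    noise = list(type = "none"), seed = 5L)
}

torso_sim_nonoise <- function() {
  cached("torso16_nonoise", simulate_gated(
    torso_preset("torso16", noise = list(type = "none"))))
}

healthy_mask_from <- function(sim, margin_mm = 10) {
  liver <- sim$liver_mask
  excl <- empty_mask(liver$geometry)
  for (ph in sim$truth)
    for (tr in ph)
      excl$values <- excl$values | tr$values
  excl <- expand_mask(excl, margin_spec(margin_mm, margin_mm))
  binary_mask(liver$values & !excl$values, liver$geometry)
}
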