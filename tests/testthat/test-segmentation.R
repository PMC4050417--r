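test_that("threshold segmentation is strict and exact on noiseless spheres", {
  g <- grid_geometry(c(40, 40, 40), spacing = c(2, 2, 2))
  uni <- suv_image(array(2.97, g$shape), g)
  expect_equal(volume_cc(threshold_segment(uni, 2.97)), 0)  # strictly greater

  center <- g$origin + (g$shape - 1) * g$spacing / 2
  sph <- sphere_mask_centres(g, center, 12)
  img <- suv_image(array(2.97, g$shape) + (7.9 - 2.97) * sph$values, g)
  seg <- threshold_segment(img, 2.97)
  expect_identical(seg$values, sph$values)
  expect_error(threshold_segment(img, 0), "positive")
})

test_that("segmentation of a blurred sphere matches the analytic iso-volume", {
  g <- grid_geometry(c(64, 64, 64), spacing = c(2, 2, 2))
  center <- g$origin + (g$shape - 1) * g$spacing / 2
  spec <- phantom_spec(g,
    compartments = list(compartment_spec("ellipsoid", center, suv = 2.97,
                                         semiaxes_mm = c(60, 60, 60),
                                         name = "liver")),
    spheres = list(sphere_spec(center, suv = 7.9, radius_mm = 12)),
    psf_fwhm_mm = 6, n_phases = 1, noise = list(type = "none"))
  ph <- simulate_gated(spec)$series$phases[[1]]
  sigma <- 6 / (2 * sqrt(2 * log(2)))
  vol <- volume_cc(threshold_segment(ph, 4.0))
  expect_lt(abs(vol - analytic_blurred_sphere_volume(12, 7.9, 2.97, sigma, 4.0)) /
              analytic_blurred_sphere_volume(12, 7.9, 2.97, sigma, 4.0), 0.03)
})

test_that("segmentation is monotone in the threshold", {
  set.seed(3)
  g <- small_geometry(20)
  img <- suv_image(array(abs(rnorm(20^3, 3, 1)), g$shape), g)
  taus <- c(2, 2.5, 3, 3.5, 4.5)
  masks <- lapply(taus, function(t) threshold_segment(img, t))
  for (i in seq_len(length(taus) - 1))
    expect_true(all(masks[[i + 1]]$values <= masks[[i]]$values))
})

test_that("lesion labeling finds components, filters specks, matches brute force", {
  g <- grid_geometry(c(24, 24, 24), spacing = c(2, 2, 2))
  s1 <- sphere_mask_centres(g, c(12, 12, 12), 8)
  s2 <- sphere_mask_centres(g, c(34, 34, 34), 6)
  both <- mask_union(s1, s2)
  ls <- label_lesions(both, min_volume_cc = 0.1)
  expect_equal(ls$n, 2L)
  expect_setequal(ls$stats$n_voxels, c(sum(s1$values), sum(s2$values)))

  # single-voxel speck below min volume is removed (0.008 cc < 0.1 cc)
  speck <- empty_mask(g)
  speck$values[3, 3, 20] <- TRUE
  expect_equal(label_lesions(speck, 0.1)$n, 0L)
  expect_equal(label_lesions(speck, 0)$n, 1L)

  # scattered specks + one large sphere, min volume 0.5 cc
  set.seed(8)
  scattered <- empty_mask(g)
  scattered$values[cbind(sample(24, 30, TRUE), sample(24, 30, TRUE),
                         sample(24, 30, TRUE))] <- TRUE
  scattered <- mask_diff(scattered, expand_mask(s1, margin_spec(6, 6)))
  combo <- mask_union(s1, scattered)
  brute <- brute_components(combo)
  sizes <- table(brute[brute > 0])
  expect_equal(label_lesions(combo, 0.5)$n,
               sum(sizes * voxel_volume_cc(g) >= 0.5))
  # label partition itself agrees with brute-force BFS components
  ls_all <- label_lesions(combo, 0)
  expect_equal(ls_all$n, length(sizes))
  relabel <- interaction(ls_all$labels, brute, drop = TRUE)
  expect_equal(length(levels(relabel)), length(sizes) + 1L)
})

test_that("26-connectivity joins diagonal neighbours", {
  g <- small_geometry(6)
  m <- empty_mask(g)
  m$values[2, 2, 2] <- TRUE
  m$values[3, 3, 3] <- TRUE   # corner-adjacent
  expect_equal(label_lesions(m, 0)$n, 1L)
})

test_that("lesion matching tracks identity, motion, and absence", {
  g <- grid_geometry(c(32, 32, 48), spacing = c(2, 2, 2))
  mk_set <- function(z_off) {
    m <- sphere_mask_centres(g, c(31, 31, 40 + z_off), 10)
    label_lesions(m, 0.1)
  }
  # identical sets in all phases -> identity correspondence
  same <- replicate(6, mk_set(0), simplify = FALSE)
  corr <- match_lesions(same)
  expect_equal(dim(corr$phase_label), c(1L, 6L))
  expect_true(all(corr$phase_label == 1L))

  # sphere translating 8 mm craniocaudally between adjacent phases
  moving <- lapply(seq(0, 40, by = 8), function(z) mk_set(z - 20))
  corr_m <- match_lesions(moving)
  expect_equal(nrow(corr_m$phase_label), 1L)
  expect_true(all(!is.na(corr_m$phase_label)))

  # lesion present in exactly one phase
  one_phase <- c(list(mk_set(0)),
                 replicate(5, label_lesions(empty_mask(g), 0.1),
                           simplify = FALSE))
  corr_1 <- match_lesions(one_phase)
  expect_equal(sum(!is.na(corr_1$phase_label[1, ])), 1L)
})

test_that("BITV is the union over phases and behaves under motion", {
  g <- grid_geometry(c(32, 32, 48), spacing = c(2, 2, 2))
  mk_mask <- function(z_off) sphere_mask_centres(g, c(31, 31, 46 + z_off), 10)

  # static lesion: BITV equals the per-phase BTV
  static_sets <- replicate(6, label_lesions(mk_mask(0), 0.1), simplify = FALSE)
  bitv_s <- build_bitv(match_lesions(static_sets), 1)
  expect_equal(volume_cc(bitv_s), volume_cc(mk_mask(0)))

  # two disjoint positions: volumes add
  two <- lapply(c(-14, -14, -14, 14, 14, 14),
                function(z) label_lesions(mk_mask(z), 0.1))
  bitv_2 <- build_bitv(match_lesions(two, capture_radius_mm = 30), 1)
  expect_equal(volume_cc(bitv_2), volume_cc(mk_mask(-14)) + volume_cc(mk_mask(14)))

  # oscillating sphere: BITV equals the brute-force union to the voxel
  offs <- 7.5 * cos(2 * pi * ((1:6) - 0.5) / 6)
  sets <- lapply(offs, function(z) label_lesions(mk_mask(z), 0.1))
  corr <- match_lesions(sets)
  bitv <- build_bitv(corr, 1)
  brute <- Reduce(mask_union, lapply(offs, mk_mask))
  expect_identical(bitv$values, brute$values)
  # superset of each phase, volume >= max phase volume
  for (z in offs)
    expect_true(all(bitv$values >= mk_mask(z)$values))
  expect_error(build_bitv(corr, 99), "unknown lesion id")
})

test_that("BITV volume is non-decreasing in motion amplitude", {
  vols <- vapply(c(0, 5, 10, 15), function(a) {
    sim <- simulate_gated(ladder_spec(a))
    sets <- lapply(sim$series$phases, function(ph)
      label_lesions(threshold_segment(ph, 4.45), 0.1))
    volume_cc(build_bitv(match_lesions(sets), 1))
  }, numeric(1))
  expect_true(all(diff(vols) > 0))
})

test_that("seeded non-gated BTV picks the right component or warns empty", {
  g <- grid_geometry(c(40, 40, 40), spacing = c(2, 2, 2))
  blob <- sphere_mask_centres(g, c(39, 39, 39), 9)
  img <- suv_image(array(2, g$shape) + 4 * blob$values, g)
  got <- nongated_btv(img, 4, seed_mm = c(39, 39, 39))
  expect_identical(got$values, blob$values)
  # near miss within capture radius still resolves
  got2 <- nongated_btv(img, 4, seed_mm = c(39, 39, 52))
  expect_identical(got2$values, blob$values)
  # far from any blob: empty with a warning flag
  expect_warning(far <- nongated_btv(img, 4, seed_mm = c(5, 5, 5)),
                 "empty mask")
  expect_equal(volume_cc(far), 0)
  expect_true(isTRUE(attr(far, "no_lesion_found")))
  expect_error(nongated_btv(img, 4, seed_mm = c(500, 0, 0)), "outside")
})

test_that("a small moving lesion can vanish from the time-averaged image", {
  # sphere R = 5 mm, SUV ~1.5x threshold, amplitude 2R: gated phases catch
  # it, the motion-blurred non-gated image never crosses the threshold
  g <- grid_geometry(c(48, 48, 64), spacing = c(2, 2, 2))
  center <- g$origin + (g$shape - 1) * g$spacing / 2
  tau <- 4.45
  spec <- phantom_spec(g,
    compartments = list(compartment_spec("ellipsoid", center, suv = 2.97,
                                         semiaxes_mm = c(42, 42, 58),
                                         name = "liver")),
    spheres = list(sphere_spec(center, suv = 1.5 * tau, radius_mm = 5)),
    amplitude_mm = 10, psf_fwhm_mm = 6, noise = list(type = "none"))
  sim <- simulate_gated(spec)
  ng <- simulate_nongated(sim$series)
  per_phase_max <- vapply(sim$series$phases,
                          function(p) max(p$values), numeric(1))
  expect_gt(max(per_phase_max), tau)              # >= 1 gated phase sees it
  expect_lt(max(ng$values), tau)                  # non-gated never does
  expect_warning(miss <- nongated_btv(ng, tau, center), "empty mask")
  expect_equal(volume_cc(miss), 0)
})
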