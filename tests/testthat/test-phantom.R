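test_that("static unblurred phantom phases are identical with exact SUVmax", {
  g <- grid_geometry(c(40, 40, 40), spacing = c(2, 2, 2))
  center <- g$origin + (g$shape - 1) * g$spacing / 2
  spec <- phantom_spec(g, ambient_suv = 1,
                       spheres = list(sphere_spec(center, suv = 6, radius_mm = 9)),
                       amplitude_mm = 0, psf_fwhm_mm = 0,
                       noise = list(type = "none"))
  sim <- simulate_gated(spec)
  expect_length(sim$series$phases, 6L)
  for (p in 2:6)
    expect_identical(sim$series$phases[[p]]$values, sim$series$phases[[1]]$values)
  expect_equal(max(sim$series$phases[[1]]$values), 6)
})

test_that("simulated central profile matches the analytic blurred sphere", {
  sim <- torso_sim_nonoise()
  ph <- sim$series$phases[[1]]
  g <- ph$geometry
  sph <- sim$spec$spheres[[1]]
  sigma <- sim$spec$psf_fwhm_mm / (2 * sqrt(2 * log(2)))
  co <- axis_coords(g)
  ci <- vapply(1:3, function(a)
    which.min(abs(list(co$x, co$y, co$z)[[a]] - sph$center_mm[a])), integer(1))
  # radial samples along x through the sphere centre
  for (dx_vox in c(0, 2, 4, 6)) {
    r <- abs(co$x[ci[1] + dx_vox] - sph$center_mm[1])
    want <- blurred_sphere_profile(r, sph$radius_mm, sph$suv, 2.97, sigma)
    got <- ph$values[ci[1] + dx_vox, ci[2], ci[3]]
    expect_lt(abs(got - want) / want, 0.01)
  }
})

test_that("simulation is bit-identical under a fixed seed", {
  spec <- ladder_spec(8)
  spec$noise <- list(type = "scaled_poisson", scale = 0.05)
  a <- simulate_gated(spec)
  b <- simulate_gated(spec)
  for (p in seq_along(a$series$phases))
    expect_identical(a$series$phases[[p]]$values, b$series$phases[[p]]$values)
  spec2 <- spec; spec2$seed <- 99L
  c2 <- simulate_gated(spec2)
  expect_false(identical(a$series$phases[[1]]$values,
                         c2$series$phases[[1]]$values))
})

test_that("the non-gated image is the phase mean and dims moving lesions", {
  # static: non-gated equals any phase exactly
  g <- grid_geometry(c(32, 32, 32), spacing = c(2, 2, 2))
  center <- g$origin + (g$shape - 1) * g$spacing / 2
  static <- simulate_gated(phantom_spec(g, ambient_suv = 1,
    spheres = list(sphere_spec(center, 5, radius_mm = 8)),
    psf_fwhm_mm = 4, noise = list(type = "none")))
  ng_s <- simulate_nongated(static$series)
  expect_equal(ng_s$values, static$series$phases[[3]]$values, tolerance = 1e-12)

  # two-phase toy: voxel-wise mean verified directly
  s1 <- suv_image(array(1, c(4, 4, 4)), small_geometry(4))
  s2 <- suv_image(array(3, c(4, 4, 4)), small_geometry(4))
  toy <- simulate_nongated(gated_series(list(s1, s2)))
  expect_equal(toy$values, array(2, c(4, 4, 4)))

  # motion strictly dims the peak
  moving <- simulate_gated(ladder_spec(10))
  ng_m <- simulate_nongated(moving$series)
  peaks <- vapply(moving$series$phases, function(p) max(p$values), numeric(1))
  expect_lt(max(ng_m$values), max(peaks))
})

test_that("QA cylinder preset rasterizes the requested sphere and stays static", {
  g <- grid_geometry(c(48, 48, 48), spacing = c(1, 1, 1))
  spec <- jaszczak_preset(16, 8, geometry = g, psf_fwhm_mm = 0)
  expect_equal(spec$compartments[[1]]$suv, 1.23)   # matched warm background
  expect_equal(spec$contrast_ratio, 8 / 1.23)
  sim1 <- simulate_gated(spec)
  tr <- sim1$truth[[1]][[1]]
  expect_lt(abs(volume_cc(tr) - 16) / 16, 0.02)

  spec4 <- jaszczak_preset(4, 2, geometry = g)
  expect_equal(spec4$compartments[[1]]$suv, 1.17)
  expect_equal(spec4$contrast_ratio, 2 / 1.17, tolerance = 1e-12)

  expect_error(jaszczak_preset(16, 8, amplitude_mm = 5), "static")
  expect_error(jaszczak_preset(12, 8), "16, 8, 4")
})

test_that("torso preset carries the two published sphere configurations", {
  s16 <- torso_preset("torso16")
  expect_equal(s16$spheres[[1]]$suv, 7.9)
  expect_lt(abs(4 / 3 * pi * s16$spheres[[1]]$radius_mm^3 / 1000 - 16), 1e-6)
  s8 <- torso_preset("torso8")
  expect_equal(s8$spheres[[1]]$suv, 5.6)
  expect_lt(abs(4 / 3 * pi * s8$spheres[[1]]$radius_mm^3 / 1000 - 8), 1e-6)
  expect_equal(s16$contrast_ratio, 7.9 / 2.97, tolerance = 1e-12)
  liver <- Filter(function(cc) cc$name == "liver", s16$compartments)
  expect_length(liver, 1L)
})

test_that("a sphere leaving the grid under motion is rejected", {
  g <- grid_geometry(c(32, 32, 32), spacing = c(2, 2, 2))
  near_edge <- sphere_spec(c(31, 31, 55), suv = 5, radius_mm = 6)
  expect_error(phantom_spec(g, spheres = list(near_edge), amplitude_mm = 10),
               "leaves the grid")
  expect_silent(phantom_spec(g, spheres = list(near_edge), amplitude_mm = 1))
})

test_that("analytic blurred-sphere volume behaves at its limits", {
  # sigma -> 0: the true sphere for any tau in (b, A)
  expect_equal(analytic_blurred_sphere_volume(10, 5, 1, 0, 3),
               4 / 3 * pi * 1000 / 1000, tolerance = 1e-12)
  # monotone decreasing in tau; crosses the true volume
  R <- 15.63
  taus <- seq(3.2, 7, by = 0.5)
  vols <- vapply(taus, function(t)
    analytic_blurred_sphere_volume(R, 7.9, 2.97, 4, t), numeric(1))
  expect_true(all(diff(vols) < 0))
  expect_gt(vols[1], 16)                       # tau near background: inflated
  expect_lt(vols[length(vols)], 16)            # tau near peak: shrunken
  # no iso-surface outside (b, peak)
  expect_error(analytic_blurred_sphere_volume(10, 5, 1, 3, 0.9), "iso-surface")
  expect_error(analytic_blurred_sphere_volume(10, 5, 1, 3, 5.1), "iso-surface")
})

test_that("closed-form profile agrees with numeric radial integration", {
  for (prm in list(c(R = 10, A = 5, b = 1, s = 3),
                   c(R = 15.63, A = 7.9, b = 2.97, s = 2.548))) {
    r <- unname(c(0, 2, 7.5, prm["R"], prm["R"] + 4, prm["R"] + 9))
    want <- numeric_blurred_profile(r, prm["R"], prm["A"], prm["b"], prm["s"])
    got <- blurred_sphere_profile(r, prm["R"], prm["A"], prm["b"], prm["s"])
    expect_equal(got, want, tolerance = 1e-7)
  }
})

test_that("threshold at background inflates measured volumes (partial volume)", {
  # the mechanism behind overestimated phantom volumes: tau just above b
  v_eps <- analytic_blurred_sphere_volume(15.63, 7.9, 2.97, 4, 3.05)
  expect_gt(v_eps, 16)
})
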