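test_that("pipeline configuration validates and round-trips through YAML", {
  cfg <- pipeline_config()
  expect_equal(cfg$n_phases, 6L)
  expect_equal(cfg$ptvg_margin_mm, 3)
  expect_equal(cfg$ptv_radial_mm, 5)
  expect_equal(cfg$ptv_cc_mm, 10)
  expect_equal(cfg$min_lesion_volume_cc, 0.1)
  expect_equal(cfg$capture_radius_mm, 15)
  expect_error(pipeline_config(reference_phase = 7), "index")

  p <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("reference_phase: 2", "ptvg_margin_mm: 4", "roi_seed: 7"), p)
  cfg2 <- read_pipeline_config(p)
  expect_equal(cfg2$reference_phase, 2L)
  expect_equal(cfg2$ptvg_margin_mm, 4)
  expect_equal(cfg2$n_phases, 6L)
})

test_that("gated workflow nests volumes on a static phantom", {
  sim <- simulate_gated(ladder_spec(0))
  healthy <- healthy_mask_from(sim)
  wf <- run_gated_workflow(sim$series, healthy, pipeline_config(), tau = 4.45)
  expect_equal(nrow(wf$records), 1L)
  btv1 <- volume_cc(threshold_segment(sim$series$phases[[1]], 4.45))
  expect_equal(wf$records$bitv_cc, btv1)          # zero motion: BITV = BTV
  expect_gt(wf$records$ptvg_cc, wf$records$bitv_cc)
  expect_equal(wf$records$n_phases_present, 6L)
})

test_that("gated workflow grows the BITV under motion and is reproducible", {
  sim0 <- simulate_gated(ladder_spec(0))
  sim10 <- simulate_gated(ladder_spec(10))
  healthy <- healthy_mask_from(sim10)
  wf0 <- run_gated_workflow(sim0$series, healthy, pipeline_config(), tau = 4.45)
  wf10 <- run_gated_workflow(sim10$series, healthy, pipeline_config(), tau = 4.45)
  expect_gt(wf10$records$bitv_cc, wf0$records$bitv_cc)

  rerun <- run_gated_workflow(sim10$series, healthy, pipeline_config(), tau = 4.45)
  expect_identical(rerun$records, wf10$records)
  expect_identical(rerun$bitv[[1]]$values, wf10$bitv[[1]]$values)
})

test_that("gated workflow derives its threshold from the protocol when noisy", {
  sim <- cached("torso16_noisy",
                simulate_gated(torso_preset("torso16", seed = 11L)))
  healthy <- healthy_mask_from(sim)
  wf <- run_gated_workflow(sim$series, healthy,
                           pipeline_config(reference_phase = 1, roi_seed = 4))
  expect_s3_class(wf$threshold, "background_estimate")
  expect_gt(wf$threshold$threshold, 2.97)        # noise lifts SUVmax above b
  expect_true(wf$threshold$n_rois %in% c(3L, 5L))
  expect_gte(nrow(wf$records), 1L)
})

test_that("non-gated workflow honours CTV overrides and liver clipping", {
  sim <- simulate_gated(ladder_spec(0))
  ng <- simulate_nongated(sim$series)
  liver <- sim$liver_mask
  cfg <- pipeline_config()

  # BTV fully inside liver: automated CTV equals BTV
  wf <- run_nongated_workflow(ng, liver, config = cfg, tau = 4.45)
  expect_equal(wf$records$ctv_cc, wf$records$btv_cc)
  expect_gt(wf$records$ptv_cc, wf$records$ctv_cc)

  # explicit CTV override: PTV is exactly its anisotropic expansion
  override <- sphere_mask_centres(ng$geometry, c(47, 47, 63), 7)
  wf_o <- run_nongated_workflow(ng, liver, ctv_override = list(override),
                                config = cfg, tau = 4.45)
  expect_identical(wf_o$ptv[[1]]$values,
                   expand_mask(override, margin_spec(5, 10))$values)

  # BTV straddling the liver boundary: CTV is the strict intersection
  small_liver <- sphere_mask_centres(ng$geometry, c(47, 47, 38), 25)
  wf_s <- run_nongated_workflow(ng, small_liver, config = cfg, tau = 4.45)
  expect_lt(wf_s$records$ctv_cc, wf_s$records$btv_cc)
  expect_equal(wf_s$records$ctv_cc,
               volume_cc(mask_intersect(wf_s$btv[[1]], small_liver)))
})

test_that("comparison report assembles ratios, tests and exceptions", {
  gated <- data.frame(lesion = 1:3, bitv_cc = c(4, 6, 10),
                      ptvg_cc = c(8, 11, 16), n_phases_present = 6L)
  nong <- data.frame(lesion = 1:3, btv_cc = c(2, 5, 9),
                     ctv_cc = c(2, 5, 9), ptv_cc = c(12, 14, 15))
  rep <- compare_report(gated, nong)
  expect_equal(rep$per_lesion$ptv_ptvg_pct, c(150, 127, 94))
  expect_equal(rep$per_lesion$bitv_btv_pct, c(200, 120, 111))
  expect_equal(rep$exceptions, 1L)               # lesion 3: PTVg >= PTV
  expect_s3_class(rep$tests$ptv_vs_ptvg, "paired_test_result")

  # identical volumes: ratios 100, degenerate Wilcoxon p = 1
  same <- data.frame(lesion = 1, bitv_cc = 5, ptvg_cc = 9, btv_cc = 5,
                     ctv_cc = 5, ptv_cc = 9)
  rep2 <- compare_report(same[, c("lesion", "bitv_cc", "ptvg_cc")],
                         same[, c("lesion", "btv_cc", "ctv_cc", "ptv_cc")])
  expect_equal(rep2$per_lesion$ptv_ptvg_pct, 100)
  expect_true(rep2$tests$ptv_vs_ptvg$degenerate)
  expect_equal(rep2$tests$ptv_vs_ptvg$p, 1)
  # single lesion: summary equals the row
  expect_equal(rep2$summary$columns$mean[rep2$summary$columns$column == "ptv_cc"], 9)

  expect_error(compare_report(gated, nong[1:2, ]), "matching lesion ids")
})

test_that("reports serialize to schema-shaped JSON and CSV", {
  gated <- data.frame(lesion = 1:2, bitv_cc = c(4, 6), ptvg_cc = c(8, 11),
                      n_phases_present = 6L)
  nong <- data.frame(lesion = 1:2, btv_cc = c(2, 5), ctv_cc = c(2, 5),
                     ptv_cc = c(12, 14))
  rep <- compare_report(gated, nong)
  jp <- withr::local_tempfile(fileext = ".json")
  cp <- withr::local_tempfile(fileext = ".csv")
  write_report(rep, jp, cp)
  back <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_named(back, c("per_lesion", "summary", "tests", "exceptions"))
  expect_equal(back$exceptions, rep$exceptions)
  expect_equal(back$tests$ptv_vs_ptvg$p, rep$tests$ptv_vs_ptvg$p)
  expect_equal(nrow(utils::read.csv(cp)), 2L)
})

test_that("full gated-vs-nongated comparison reproduces the expected direction", {
  # 5 mm excursion: half the conventional 10 mm craniocaudal margin, the
  # regime those margins were designed to overbound, so gated planning
  # should shrink the PTV; the BITV still exceeds the motion-blurred BTV
  sim <- simulate_gated(ladder_spec(5))
  healthy <- healthy_mask_from(sim)
  wf_g <- run_gated_workflow(sim$series, healthy, pipeline_config(), tau = 4.45)
  ng <- simulate_nongated(sim$series)
  wf_n <- run_nongated_workflow(ng, sim$liver_mask, config = pipeline_config(),
                                tau = 4.45)
  rep <- compare_report(wf_g$records, wf_n$records)
  expect_gt(rep$per_lesion$bitv_btv_pct, 100)
  expect_gt(rep$per_lesion$ptv_ptvg_pct, 100)

  # at 10 mm excursion — the margin itself — the conventional PTV no longer
  # reliably covers more than the gated PTVg (the clinical exception case)
  sim10 <- simulate_gated(ladder_spec(10))
  wf_g10 <- run_gated_workflow(sim10$series, healthy, pipeline_config(),
                               tau = 4.45)
  expect_gt(wf_g10$records$bitv_cc, wf_g$records$bitv_cc)
})
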