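#!/usr/bin/env Rscript

# Phantom evaluation of the healthy-background SUVmax threshold method.
#
# Two experiments on simulated QA phantoms:
#   1. Hot spheres (16/8/4 cc at SUV 2/4/8) in a warm cylinder, segmented at
#      the background SUVmax measured with the clinical ROI protocol — the
#      volume errors show how threshold-at-background delineation behaves
#      across contrast.
#   2. The torso configurations (16 cc @ SUV 7.9 and 8 cc @ SUV 5.6 on a
#      2.97 liver background): noiseless threshold-at-background
#      segmentation compared against the analytic blurred-sphere oracle,
#      isolating the partial-volume mechanism that inflates the volumes.
#
# Writes results/phantom_evaluation.csv and results/torso_oracle.csv.

suppressPackageStartupMessages(library(petitv))
dir.create("results", showWarnings = FALSE)
set.seed(20260922)

sigma_psf <- 6 / (2 * sqrt(2 * log(2)))

## ---- 1. warm-cylinder sphere sweep with the ROI protocol ------------------
rows <- list()
for (vol_cc in c(16, 8, 4)) {
  for (suv in c(2, 4, 8)) {
    g <- grid_geometry(c(64, 64, 64), spacing = c(2, 2, 2))
    spec <- jaszczak_preset(vol_cc, suv, geometry = g,
                            noise = list(type = "scaled_poisson", scale = 0.05),
                            seed = 100 + vol_cc + suv)
    spec$n_phases <- 1L                      # static phantom: one bin suffices
    sim <- simulate_gated(spec)
    img <- sim$series$phases[[1]]
    truth <- sim$truth[[1]][[1]]
    healthy <- mask_diff(sim$liver_mask,
                         expand_mask(truth, margin_spec(14, 14)))
    est <- background_threshold(
      sample_background_rois(img, healthy, 20, k = 3, seed = 7),
      function(n) utils::tail(
        sample_background_rois(img, healthy, 20, k = 5, seed = 7), n))
    seg <- label_lesions(threshold_segment(img, est$threshold), 0.1)
    measured <- if (seg$n) max(seg$stats$volume_cc) else 0
    rows[[length(rows) + 1]] <- data.frame(
      sphere_cc = vol_cc, sphere_suv = suv,
      background_suv = spec$compartments[[1]]$suv,
      contrast = round(spec$contrast_ratio, 2),
      threshold_suv = round(est$threshold, 2), n_rois = est$n_rois,
      measured_cc = round(measured, 1),
      error_pct = round(100 * (measured - vol_cc) / vol_cc))
  }
}
sweep_tab <- do.call(rbind, rows)
write.csv(sweep_tab, "results/phantom_evaluation.csv", row.names = FALSE)

cat("Warm-cylinder sphere sweep (threshold = background SUVmax protocol):\n")
print(sweep_tab, row.names = FALSE)
cat(sprintf("\nVolume errors span %d%% to %d%%: low-contrast spheres are mismeasured\nworst, because the background-level threshold sits deep in the blurred\nedge profile.\n\n",
            min(sweep_tab$error_pct), max(sweep_tab$error_pct)))

## ---- 2. torso configurations vs the analytic oracle -----------------------
torso_rows <- lapply(c("torso16", "torso8"), function(cfg) {
  spec <- torso_preset(cfg, noise = list(type = "none"))
  sim <- simulate_gated(spec)
  sph <- spec$spheres[[1]]
  true_cc <- 4 / 3 * pi * sph$radius_mm^3 / 1000
  tau <- 2.97 + 0.23                        # background + a small offset
  measured <- volume_cc(threshold_segment(sim$series$phases[[1]], tau))
  oracle <- analytic_blurred_sphere_volume(sph$radius_mm, sph$suv, 2.97,
                                           sigma_psf, tau)
  data.frame(config = cfg, sphere_cc = round(true_cc), sphere_suv = sph$suv,
             threshold_suv = tau, measured_cc = round(measured, 1),
             oracle_cc = round(oracle, 1),
             bias_pct = round(100 * (measured - true_cc) / true_cc),
             vs_oracle_pct = round(100 * (measured - oracle) / oracle, 2))
})
torso_tab <- do.call(rbind, torso_rows)
write.csv(torso_tab, "results/torso_oracle.csv", row.names = FALSE)

cat("Torso configurations, noiseless threshold just above background:\n")
print(torso_tab, row.names = FALSE)
cat("\nBoth spheres are overestimated (positive bias), and the measured volume\nagrees with the analytic blurred-sphere oracle to well under 3%: the\noverestimation is fully explained by the PSF spreading sphere signal\nabove a threshold that sits close to the background level.\n")
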