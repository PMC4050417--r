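#!/usr/bin/env Rscript

# End-to-end comparison of the two planning workflows on simulated gated
# acquisitions: gated (threshold -> per-phase BTVs -> BITV -> +3 mm PTVg)
# versus conventional (non-gated BTV -> CTV -> +5/10 mm PTV), across a
# ladder of craniocaudal motion amplitudes, plus the small-lesion
# demonstration in which only the gated exam detects the tumor.
#
# Writes results/workflow_comparison.csv and results/workflow_report.json.

suppressPackageStartupMessages(library(petitv))
dir.create("results", showWarnings = FALSE)

make_spec <- function(amplitude_mm) {
  g <- grid_geometry(c(48, 48, 64), spacing = c(2, 2, 2))
  center <- g$origin + (g$shape - 1) * g$spacing / 2
  phantom_spec(g,
    compartments = list(compartment_spec("ellipsoid", center, suv = 2.97,
                                         semiaxes_mm = c(42, 42, 58),
                                         name = "liver")),
    spheres = list(sphere_spec(center, suv = 7.9, radius_mm = 10)),
    amplitude_mm = amplitude_mm, psf_fwhm_mm = 6,
    noise = list(type = "none"), seed = 17L)
}

tau <- 4.45   # representative individualized threshold
cfg <- pipeline_config()
rows <- list()
last_report <- NULL
for (amp in c(0, 5, 10, 15)) {
  sim <- simulate_gated(make_spec(amp))
  wf_g <- run_gated_workflow(sim$series, sim$liver_mask, cfg, tau = tau)
  ng <- simulate_nongated(sim$series)
  wf_n <- run_nongated_workflow(ng, sim$liver_mask, config = cfg, tau = tau)
  rep <- compare_report(wf_g$records, wf_n$records)
  last_report <- rep
  rows[[length(rows) + 1]] <- data.frame(
    amplitude_mm = amp,
    btv_cc = rep$per_lesion$btv_cc, bitv_cc = rep$per_lesion$bitv_cc,
    ptv_cc = rep$per_lesion$ptv_cc, ptvg_cc = rep$per_lesion$ptvg_cc,
    bitv_btv_pct = rep$per_lesion$bitv_btv_pct,
    ptv_ptvg_pct = rep$per_lesion$ptv_ptvg_pct)
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/workflow_comparison.csv", row.names = FALSE)
write_report(last_report, "results/workflow_report.json")

cat("Gated vs conventional planning across motion amplitudes (16 cc-class\nsphere, SUV 7.9, threshold 4.45):\n")
print(tab, row.names = FALSE)
cat("\nThe BITV grows with motion while the motion-blurred non-gated BTV\nshrinks, so BITV/BTV rises steeply. The conventional PTV exceeds the\ngated PTVg while the fixed 10 mm craniocaudal margin overbounds the\nactual excursion; once the excursion reaches the margin the advantage\ndisappears — the mechanism behind the clinical exception case.\n\n")

## ---- small moving lesion: detected only on the gated exam -----------------
g <- grid_geometry(c(48, 48, 64), spacing = c(2, 2, 2))
center <- g$origin + (g$shape - 1) * g$spacing / 2
sim_small <- simulate_gated(phantom_spec(g,
  compartments = list(compartment_spec("ellipsoid", center, suv = 2.97,
                                       semiaxes_mm = c(42, 42, 58),
                                       name = "liver")),
  spheres = list(sphere_spec(center, suv = 1.5 * tau, radius_mm = 5)),
  amplitude_mm = 10, psf_fwhm_mm = 6, noise = list(type = "none"),
  seed = 17L))
hits <- vapply(sim_small$series$phases, function(p) any(p$values > tau),
               logical(1))
ng_small <- simulate_nongated(sim_small$series)
cat(sprintf("Small lesion (10 mm diameter, SUV %.2f, 10 mm excursion):\n  supra-threshold in %d of 6 gated phases; non-gated peak SUV %.2f < %.2f\n  -> invisible on the non-gated exam, found only with gating.\n",
            1.5 * tau, sum(hits), max(ng_small$values), tau))
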