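# petitv

Individualized threshold-based target-volume delineation on
respiratory-gated (4D) FDG-PET for liver SBRT planning — with the phantom
simulation and cohort statistics needed to validate it.

## The problem

Liver metastases move up to 2 cm with respiration. On a non-gated PET exam
the tumor is imaged time-averaged: activity smears along the motion path,
peak SUV falls, and small lesions can vanish below any segmentation
threshold. Conventional SBRT planning compensates with generic margins
(5 mm radial, 10 mm craniocaudal) around a clinician-edited target. A
respiratory-gated PET, binned into six phases over the breathing cycle,
freezes the motion instead, so the internal extent of the target can be
measured rather than guessed.

`petitv` implements both planning chains end to end:

- **Individualized threshold**: the segmentation threshold τ is the
  healthy-liver background SUVmax, measured in 20–30 cc ROIs with the
  3-or-5-ROI repetition protocol (spread < 0.1 → 3 ROIs; spread in
  [0.1, 0.2] → 5 ROIs; larger → protocol failure). A voxel is tumor iff
  SUV > τ, with SUV body-weight normalized.
- **Gated chain**: τ applied to each of the six phases → per-phase BTVs →
  cross-phase lesion matching → **BITV** = union of the per-phase masks →
  **PTVg** = BITV + 3 mm isotropic set-up margin.
- **Conventional chain**: non-gated BTV → CTV (manual mask, or BTV clipped
  to the liver) → **PTV** = CTV + 5 mm radial / 10 mm craniocaudal, via
  dilation with an ellipsoidal kernel in physical millimetres.
- **Statistics**: paired two-tailed Wilcoxon signed-rank tests computed
  exactly (zeros dropped, mid-ranks, full sign-assignment enumeration by
  dynamic programming), cohort summaries with ratio-of-means, median/range.
- **Synthetic gated phantom**: hot spheres in warm liver/lung/body
  compartments, craniocaudal cosine motion, intra-bin time averaging,
  Gaussian PSF blur, correlated Poisson-like noise — plus a closed-form
  blurred-sphere oracle for validating threshold segmentation analytically.

## Worked example

Cohort statistics on the packaged reference cohort (8 patients, 14 liver
metastases from a published SBRT pilot cohort):

```r
library(petitv)
vols <- load_reference_cohort("volumes")
s <- summarize_volumes(vols)
round(s$ratio_of_means)
#> ptv_ptvg bitv_btv
#>      150      131
wilcoxon_exact(vols$ptv_cc, vols$ptvg_cc)
#> Wilcoxon signed-rank (exact): W = 10, n = 14 (14 non-zero), two-tailed p = 0.005249
wilcoxon_exact(vols$bitv_cc, vols$btv_cc)
#> Wilcoxon signed-rank (exact): W = 8, n = 14 (14 non-zero), two-tailed p = 0.003052
count_exceptions(vols)
#> [1] 1
```

The gated planning volumes are significantly smaller than conventional ones
(PTV/PTVg ratio-of-means 150%, p ≈ 0.0052) even though the gated internal
target volume is *larger* than the motion-blurred non-gated BTV (BITV/BTV
131%, p ≈ 0.0031); exactly one lesion (lung-adjacent) had PTVg ≥ PTV.

A simulated gated acquisition and the full gated workflow:

```r
spec <- torso_preset("torso16", amplitude_mm = 10, noise = list(type = "none"))
sim <- simulate_gated(spec)          # 6 phases, 96^3 @ 2 mm, ~3 s
wf <- run_gated_workflow(sim$series, sim$liver_mask, pipeline_config(),
                         tau = 4.45)
wf$records
#>   lesion bitv_cc ptvg_cc n_phases_present
#> 1      1  32.896  47.552                6
```

The analysis scripts under `analysis/` run the three studies in order —
phantom evaluation of the threshold method (`01`), cohort statistics
(`02`), and the gated-vs-conventional workflow comparison across motion
amplitudes including the small-lesion miss demonstration (`03`) — writing
their tables under `results/`.

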