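---
title: "Individualized threshold delineation on respiratory-gated PET for liver SBRT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individualized threshold delineation on respiratory-gated PET for liver SBRT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petitv)
```

## The problem

Liver metastases move with respiration — excursions of up to 2 cm during
quiet breathing. A non-gated FDG-PET acquisition therefore images a
time-averaged tumor: activity is smeared along the motion path, peak SUV
drops, and small lesions can disappear below any segmentation threshold. For
stereotactic body radiotherapy (SBRT), where dose gradients are steep and
healthy-liver sparing limits dose escalation, this matters twice over: the
*internal* extent of the moving target is underestimated, and conventional
planning compensates with generic margins (5 mm radial, 10 mm craniocaudal)
that may be simultaneously too large radially and poorly centred.

Respiratory-gated (4D) PET bins the acquisition into respiratory phases —
six here, equally distributed over the breathing cycle — so each phase image
is nearly motion-frozen. `petitv` implements a complete planning pipeline on
such data and its non-gated counterpart, plus the phantom simulation and
cohort statistics needed to validate it.

## The delineation model

**Individualized threshold.** Tumor membership is defined relative to the
patient's own healthy-liver uptake: the segmentation threshold $\tau$ is the
SUVmax of healthy liver background, and a voxel belongs to the tumor iff
$\mathrm{SUV} > \tau$ (strictly). SUV is body-weight normalized:

$$\mathrm{SUV}(v) = \frac{C(v)\,[\mathrm{Bq/mL}] \cdot m\,[\mathrm{g}]}
{A_0 \cdot 2^{-\Delta t / T_{1/2}}\,[\mathrm{Bq}]}$$

with $C$ the activity concentration, $m$ body weight, $A_0$ injected
activity, $\Delta t$ the uptake delay (60 min default) and $T_{1/2}$ the
F-18 half-life (109.77 min).

**Background protocol.** $\tau$ is measured as the SUVmax within 20–30 cc
spherical ROIs placed in healthy liver. Three ROIs are used when their
SUVmax values differ by less than 0.1; two more are added when the spread is
in $[0.1, 0.2]$; a spread above 0.2 is a protocol failure. The published
protocol does not state how the repeated measurements are aggregated; we use
the arithmetic mean, since the repetition rule exists to stabilize a noisy
estimate and averaging is the estimator that does so. On gated data the
protocol runs on the *reference phase* — the phase matching the planning
CT's respiratory state — which is explicit configuration
(`pipeline_config(reference_phase = )`), because the phase-matching
criterion is an acquisition property the software cannot infer.

**Volumes.** Applying $\tau$ to each gated phase yields six per-phase
biological target volumes (BTVs). Per-phase lesions are labelled as
26-connected components, matched across phases (greedy maximal voxel
overlap, falling back to nearest centroid within 15 mm), and each lesion's
**BITV** (biological internal target volume) is the voxel-wise **union** of
its per-phase masks — "adding" the six volumes in the set sense, which is
what an internal target volume means. The gated planning volume **PTVg** is
the BITV expanded isotropically by 3 mm (set-up margin). The conventional
chain segments the non-gated image with its own protocol-derived threshold,
restricts the BTV to a clinical target volume (CTV), and expands by 5 mm
radial / 10 mm craniocaudal to a **PTV**.

**Margin expansion** is morphological dilation by the ellipsoid
$\{(dx,dy,dz) : (dx/r)^2 + (dy/r)^2 + (dz/c)^2 \le 1\}$ computed in
physical millimetres on the voxel lattice, so anisotropic grids need no
resampling. We realize it as a sparse Minkowski sum over the precomputed
ellipsoid offset kernel: on the lattice this is *exactly* the dilation the
ellipsoidal structuring element defines (the tests pin it voxel-for-voxel
against a brute-force pairwise-distance oracle), and it is equivalent to
thresholding an anisotropically scaled distance transform without needing
one. One numerical caveat is inherent to any lattice dilation: the Minkowski
sum ranges over voxel *centres*, so dilated volumes undershoot their
continuum values by a surface shell on the order of the grid's covering
radius — about 2–3% for a 13 mm sphere at 0.5–1 mm spacing, vanishing with
refinement. Volumes are voxel counts times voxel volume, with no sub-voxel
surface correction, matching what treatment-planning systems report.

**Statistics.** Gated and conventional volumes are compared per lesion with
the paired two-tailed Wilcoxon signed-rank test, computed *exactly*:
zero differences are dropped (Wilcoxon's original treatment — required to
reproduce the published threshold comparison, where one of eight pairs is
tied), absolute differences are mid-ranked, and the null distribution of the
rank sum is enumerated by dynamic programming over all $2^n$ sign
assignments (doubled ranks keep the sums integral under mid-ranks);
$p = 2P(T \le W)$ capped at 1. Beyond 25 non-zero pairs a tie-corrected
normal approximation with continuity correction is used. The cohort summary
row reports the **ratio of means** (×100), not the mean of per-lesion
ratios — the two differ by ~15 percentage points on the reference cohort,
and only the former matches a summary row computed from column means.

## Key parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| phases | 6 | — | equal bins over the breathing cycle |
| reference phase | 1 (configurable) | — | phase matching the planning CT |
| ROI volume | 20 | cc | low end of the 20–30 cc protocol range, proportionate to the phantom liver |
| PTVg margin | 3 | mm | isotropic set-up margin (population setup errors ≈ 2.3–3 mm) |
| PTV margins | 5 radial / 10 craniocaudal | mm | conventional motion + set-up recipe |
| min lesion volume | 0.1 | cc | suppresses noise specks; the smallest clinical BTV on record is 0.7 cc, seven times larger |
| capture radius | 15 | mm | lesion matching fallback; of the order of one lesion diameter |
| PSF FWHM | 6 | mm | clinical whole-body PET resolution (the 2 mm reconstruction filter is not the system resolution) |
| noise scale | 0.05 | SUV$^{1/2}$ | see below |

## What the phantom generator emulates — and what it does not

`phantom_spec` builds hot spheres in warm compartments (ellipsoids and
cylinders; body, lung, mediastinum and liver presets), moves spheres along a
craniocaudal cosine, rasterizes with 3× per-axis supersampling (so sphere
volumes converge to their analytic values), averages 5 time points per phase
bin (residual intra-gate blur; bins are centred on the motion extremes, so
phase 1 is end-inspiration), convolves with an isotropic Gaussian PSF, and
adds noise. Noise is generated as an iid Gaussian field smoothed with the
PSF kernel and renormalized to unit marginal variance — reconstructed PET
noise is correlated at the reconstruction-kernel scale, not white — then
scaled by $\sigma(v) = 0.05\sqrt{v}$ (a Poisson-like surrogate). The scale
0.05 was calibrated to the published behaviour of the background protocol
itself: with it, healthy-liver ROI SUVmax spreads fall below 0.1 for most
seeds, occasionally in $[0.1, 0.2]$, and not above 0.2 — the regime the
clinical study reports. A white-noise or higher-amplitude model produces
protocol failures that the study never observed.

The generator does **not** simulate sinograms, reconstruction, attenuation,
scatter, or irregular breathing. Consequently, passing tests demonstrate the
*geometry and logic* of the pipeline — threshold behaviour under blur,
union-over-phases, margins, statistics — on data with the right first- and
second-order structure; they do not certify performance against
reconstruction artifacts, physiological uptake heterogeneity, or baseline
drift in real exams. The physical QA ranges reported for real scanners are
therefore not numeric targets here; what is reproduced is their mechanism
and direction (see below).

## Numerical choices and degenerate inputs

- Strict inequality ($> \tau$) means a threshold exactly at a uniform
  background segments nothing — and also that, in a *noiseless* simulation,
  the protocol threshold (= the background value exactly) would segment
  precisely the PSF tail of the sphere, inflating volumes ~3-fold. This is
  not a pathology of the implementation but of the noiseless limit: the
  protocol's SUVmax is designed to ride above background by the noise
  excursion. The phantom experiments therefore either use noise with the
  protocol, or pin $\tau$ explicitly just above background when isolating
  the partial-volume mechanism against the analytic oracle.
- The analytic blurred-sphere oracle uses the closed-form error-function
  profile of a Gaussian-convolved uniform sphere; the tests cross-check it
  against direct numeric radial integration, and the iso-surface radius is
  found by root bracketing. $\sigma = 0$ falls back to the step profile.
- Connected components use 26-connectivity (blob-like PET lesions);
  labelling order is deterministic (first-occurrence, column-major).
- All randomness (ROI placement, noise) is seeded; placement uses rejection
  sampling with whole-set restarts, because a greedy first ROI can block a
  joint placement that exists.
- Degenerate inputs have defined behaviour: empty masks volume 0, empty
  lesion sets, all-zero Wilcoxon differences give $p = 1$ with a degenerate
  flag, a seed point with no lesion in range returns an empty flagged mask
  with a warning rather than an error.

## Design choices where the protocol was open

- **CTV automation.** Clinically the CTV is a radiation oncologist's manual
  edit of the BTV. `run_nongated_workflow` accepts the manual mask
  (`ctv_override`, the faithful path) and otherwise substitutes BTV ∩ liver
  — an explicit stand-in that keeps end-to-end runs unattended while honest
  about the manual step.
- **Torso preset geometry.** The lesion sits off-centre in one liver lobe.
  A centred lesion plus its exclusion margin leaves no room for three
  disjoint 20 cc ROIs in a ~940 cc phantom liver; the off-centre layout is
  also the anatomically ordinary case.
- **BITV union on the common voxel grid** (rather than contour union in a
  planning system): all phases share one grid by construction, and a
  geometry mismatch is an error, never a resample.

## Reference-cohort quirks

The packaged cohort fixtures reproduce the published per-patient table
verbatim. Two printed values do not re-derive from their own columns: the
non-gated threshold median computes to 3.75 where the publication prints 3.8
(one-decimal rounding), and fixture volume rows are clinical measurements
that need not satisfy the margin-superset invariants pipeline output obeys.
The statistics functions report computed values; the tests assert 3.75.

## Problem sizes

The test-suite and acceptance simulations run on 48–96³ grids at 2 mm
isotropic spacing (sub-millimetre grids only for margin-convergence checks
on small volumes), six phases, five time supersamples — sizes at which a
full gated simulation takes a few seconds and the entire suite a few
minutes, while voxelization error on 8–16 cc spheres stays near or below
1%.

## Known limitations

- Single-breathing-period cosine motion; no hysteresis, drift, or amplitude
  variability.
- Volumes by voxel counting inherit lattice bias at coarse spacing (above).
- Lesion matching is volumetric-overlap greedy; pathological splits/merges
  across phases (a lesion fragmenting at threshold) can start extra tracks.
- The exact Wilcoxon treats lesions as independent pairs, mirroring the
  clinical analysis; lesions within a patient are in truth correlated, and
  a mixed-effects treatment is deliberately out of scope.
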