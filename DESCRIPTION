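Package: petitv
Title: Respiratory-Gated PET Target Volume Delineation for Liver SBRT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individualized threshold-based delineation of liver metastases on
    respiratory-gated (4D) FDG-PET for stereotactic body radiotherapy planning.
    Implements the healthy-liver background SUVmax threshold protocol, per-phase
    biological target volume (BTV) segmentation, construction of the biological
    internal target volume (BITV) as the union over the six respiratory phases,
    margin expansion into gated and conventional planning target volumes (PTVg,
    PTV), exact paired Wilcoxon signed-rank cohort statistics, and a synthetic
    gated-PET phantom generator (hot spheres in a warm liver-like background
    with craniocaudal sinusoidal motion, Gaussian PSF blur and optional noise)
    with an analytic blurred-sphere oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
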