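Package: bpequant
Title: Automated Quantification of Background Parenchymal Enhancement in
    Breast DCE-MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Fully automated quantification of fibroglandular tissue (FGT)
    and background parenchymal enhancement (BPE) from dynamic
    contrast-enhanced breast MRI. Segments the breast and the
    fibroglandular tissue on a non-fat-suppressed T1-weighted volume
    (edge-based breast extraction followed by fuzzy C-means intensity
    clustering), rigidly registers the structural scan to the DCE series,
    thresholds voxel-wise enhancement ratios computed from subtraction
    images over a configurable cutoff grid, and reports |Breast|, |FGT|,
    FGT%, |BPE| and BPE% per scan. Includes the paired pre/post cohort
    statistics used to evaluate these measures as longitudinal biomarkers
    (paired t tests with false-discovery-rate correction, two-way ANOVA
    joint contrasts, logistic-regression ROC analysis with DeLong AUC
    comparison and leave-one-out cross-validation), a ground-truthed
    digital breast phantom generator for end-to-end validation, and a
    command-line pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    e1071
Config/testthat/edition: 3
RoxygenNote: 7.3.3
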