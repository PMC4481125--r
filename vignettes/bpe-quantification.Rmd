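---
title: "Quantifying background parenchymal enhancement in breast DCE-MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying background parenchymal enhancement in breast DCE-MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bpequant)
```

## The measurement problem

On dynamic contrast-enhanced breast MRI (DCE-MRI), normal fibroglandular
tissue (FGT) takes up gadolinium and enhances — the *background
parenchymal enhancement* (BPE). BPE reflects hormonal activity of the
gland and is of interest as a longitudinal imaging biomarker, for
example around risk-reducing interventions in women at high genetic
risk. Clinically BPE is graded visually (BI-RADS categories), which is
coarse and reader-dependent; `bpequant` implements a fully automated,
volumetric alternative.

Four measures are produced per scan. With `|X|` the volume of
compartment `X` in cm^3:

- `FGT% = 100 * |FGT| / |Breast|`
- a voxel-wise enhancement ratio on the subtraction image
  (`SUB = post − pre`): `R% = 100 * I_sub / I_pre`
- `|BPE|` = the volume of FGT voxels with `R% >= R%_cutoff`
  (inclusive threshold)
- `BPE% = 100 * |BPE| / |Breast|`

Because no accepted value of `R%_cutoff` exists, everything is swept
over the grid 0%, 10%, ..., 100%; 30% serves as the representative
cutoff for single-number summaries. Early and delayed post-contrast
time points are both evaluated (SUB 1 and SUB 3): delayed frames have
had longer uptake time, so their enhancing volumes are systematically
at least as large.

## The per-scan pipeline

`quantify_scan()` chains four stages.

**Breast segmentation** (`segment_breast()`) runs on the
non-fat-suppressed T1 volume, where fat is bright and air is dark. The
body is separated from air by thresholding at the half-height between
the air and fat intensity modes, estimated by 3-class fuzzy C-means
(air / dark tissue / fat). A single 2-class Otsu threshold is offered
(`air_method = "otsu"`) but is not the default: when bright fat
dominates the histogram, the 2-class between-class-variance optimum
falls *between dark tissue and fat* rather than between air and tissue,
and dark gland or muscle is lost. The half-height choice also places
the skin surface at the 50% point of the partial-volume ramp, which is
where the true boundary sits for a symmetric point-spread. Interior
dark tissue excluded by the threshold is recovered by morphological
hole filling. The chest wall is then removed with an edge rule: in each
anterior–posterior column the posterior-most strong intensity gradient
(above a fraction `edge_frac` of the 99.9th gradient percentile) marks
the chest boundary; the per-column cuts are smoothed slice-wise with a
running median, the mask is morphologically closed
(`closing_radius = 3` voxels) and the largest connected component is
kept. `|Breast|` is the mask volume in cm^3.

**FGT segmentation** (`segment_fgt()`) clusters the T1 intensities
inside the breast with 2-class fuzzy C-means (fuzzifier `m = 2`,
tolerance `1e-5`, deterministic quantile initialisation) and assigns the
*lower*-centroid class to FGT by hard maximum membership — gland is dark
against bright fat on non-fat-suppressed T1; ties break toward FGT.
Two partial-volume guards are applied, both chosen because mixed voxels
sit between the fat and gland intensities and would otherwise be
systematically mislabelled as FGT: a 1-voxel shell at the breast
surface (`boundary_margin`) and a 2-voxel margin anterior to the
chest-wall cut (`posterior_margin`) are excluded from FGT candidacy.
If the two centroids are separated by less than 1.5 times the summed
within-cluster spreads the clustering is declared degenerate and the
FGT mask is empty: splitting unimodal noise in half yields a separation
index of about 1.3, genuinely bimodal fat/gland intensities yield far
more. This prevents an all-fat breast from acquiring a fictitious FGT
compartment.

**Registration** (`rigid_register()`). The FGT mask lives on the T1
grid but enhancement is measured on the DCE grid, and the two
acquisitions differ by patient motion — modelled as a 6-degree-of-freedom
rigid transform. The T1 and the fat-suppressed DCE pre-contrast frame
have *inverted* fat/gland contrast, so correlation-type metrics are
inappropriate; mutual information (32 x 32 joint histogram) is used.
The MI is multiplied by `min(1, overlap/0.5)`, because unweighted MI
rewards sliding one volume mostly off the other. Optimisation is
multi-resolution (downsampling factors 4, 2, 1, dropping levels that
would leave fewer than 12 voxels per axis) with derivative-free
Nelder-Mead at each level; the binned-histogram metric is only
piecewise smooth, which is why a gradient scheme is not used. Two
globalisation devices make the ±10 mm / ±10° clinical regime reliable:
a translation pre-search on a ±12 mm grid around a centre-of-mass
initialisation, and a 27-point rotation multi-start (±8° per axis) of
short Nelder-Mead runs at the coarsest level. The procedure is fully
deterministic (fixed-stride voxel sampling; the finest-level stride is
chosen to keep roughly 150k metric samples). If the optimum fails to
beat the identity transform's metric by `min_gain`, the identity is
returned with a warning flag. Masks are transferred with
nearest-neighbour interpolation (preserving binarity, and exactly
preserving subset relations such as FGT within breast); images use
trilinear interpolation.

**Enhancement and thresholding** (`enhancement_ratio()`, `bpe_mask()`).
`R%` is computed only inside the transferred FGT mask. Voxels whose
pre-contrast intensity is at or below `eps` — default `1e-6` times the
99th percentile of pre-contrast FGT intensity — are marked invalid
rather than divided: fat-suppressed pre-contrast signal can approach
zero and a handful of unguarded divisions would otherwise dominate the
enhancing-voxel count. Negative subtraction values are preserved, never
clamped; they simply fail every non-negative cutoff. `|Breast|` and
`|FGT|` are measured on the T1 grid where they are segmented, `|BPE|`
on the DCE grid where enhancement lives; all are in cm^3, so the
percentage measures are well defined across grids.

## Cohort statistics

The statistical layer mirrors how such measures are evaluated as
biomarkers in a paired pre/post-intervention cohort with a binary
outcome (developing cancer after the intervention or not):

- `paired_t()` — two-sided paired Student's t per measure, per group;
  `pvalue_profile()` sweeps it over the cutoff grid (the Manhattan-plot
  view).
- `fdr_bh()` — Benjamini–Hochberg adjustment; the family is the set of
  tests reported together (one column of the group summary).
- `anova_joint()` — two-way fixed-effects ANOVA on outcome group x
  pre/post phase; the reported p is the interaction term. A
  repeated-measures variant (`repeated = TRUE`, subject as the error
  stratum) is available because the fixed-effects reading ignores the
  pairing; the fixed-effects form is the default.
- `logistic_fit()` — maximum-likelihood logistic regression by IRLS
  (tolerance `1e-8`, at most 100 iterations), fitting the outcome on
  the relative change `(post − pre)/pre` of a measure. Records with
  `pre = 0` are excluded with a warning. Perfect separation is detected
  by a diverging linear predictor and flagged rather than iterated to
  infinity. Features are not standardised by default: the AUC of a
  univariable model is invariant to monotone rescaling.
- `roc_auc()` — the fitted probabilities are the ROC decision variable;
  AUC equals the Mann–Whitney probability with ties counted 0.5, and
  the threshold-sweep curve's trapezoidal area equals that AUC exactly.
  `auc_profile()` sweeps this over the cutoff grid.
- `delong_test()` — compares correlated AUCs (same subjects) via the
  placement-value covariance estimator with midrank ties.
- `loocv_auc()` — leave-one-out cross-validation, pooling the held-out
  probabilities into a single AUC (per-fold AUCs are undefined for a
  single held-out subject). *Caveat:* pooled LOOCV probabilities are
  pessimistically biased when a feature is uninformative — removing a
  positive subject lowers the training prevalence, so held-out
  positives systematically score lower. Under permuted labels the mean
  LOOCV AUC therefore sits well below 0.5 at small n (we measure ~0.35
  at n = 100, and an independent scikit-learn reimplementation
  reproduces this). The bias is conservative — it deflates, never
  inflates, reported cross-validated performance — and is the classic
  motivation for leave-pair-out CV, which is out of scope here.

`analyze_cohort()` assembles the group summary at the representative
cutoff (means ± SD per group and phase, paired-t p per group, FDR
columns, ANOVA interaction p, per-measure AUC) and optionally a
combined two-feature logistic model (by default relative changes of
BPE% at SUB 1 and |FGT|) whose AUC is compared against each
single-feature model by DeLong's test.

## The digital phantom: what it emulates, and what it does not

No public reference data exist for this pipeline, so validation is
against `generate_phantom()`, which builds a ground-truthed scene:

- a half-ellipsoid breast (default semi-axes 38 x 45 x 26 mm on a
  96 x 96 x 64 grid at 1 mm isotropic) on a pectoral slab occupying the
  posterior 26 mm;
- FGT as smooth random blobs (a sum of Gaussian bumps thresholded at
  the quantile that hits the target volume fraction, default 15%,
  exactly in voxel count), kept away from the skin and chest wall;
- a T1 rendering (fat 200, gland 80, muscle 60, units arbitrary) and a
  fat-suppressed DCE rendering (gland 100, fat 20, muscle 40), both
  smoothed with a sigma = 0.6 voxel Gaussian to emulate partial volume,
  with additive Gaussian noise at 2% of the bright-tissue intensity;
- enhancement applied multiplicatively, `post_k = pre * (1 + r_k/100)`
  — the minimal model consistent with the ratio definition of `R%`.
  A spatially smooth sub-region covering 40% of the FGT enhances; its
  true ratios are `r_k = max(0, mean_k + sd_k * u)` with a shared smooth
  latent field `u` and per-time-point means (40, 55, 70)% and SDs
  (18, 21, 24)%, so delayed uptake exceeds early uptake voxel-wise;
  non-enhancing tissue has true ratio 0;
- a known rigid inter-scan transform (default 3° about z plus
  (2, −3, 1) mm) displacing the DCE frames from the T1 frame; the truth
  masks and per-voxel true ratios are stored on both frames *before*
  noise, so `true_bpe_cc()` is an exact oracle.

The phantom deliberately omits bias fields, Rician noise statistics,
anatomical texture, motion between DCE time points, skin/nipple
structures and lesions. Passing the phantom recovery tests therefore
demonstrates that the arithmetic, segmentation logic, registration and
threshold sweep are correct and stable under noise and partial volume —
not that the segmentation would meet clinical accuracy on real
anatomy.

`generate_cohort()` plays the same role for the statistics: lognormal
marginals per measure and outcome group (volumes are positive with SDs
comparable to their means, which rules out normal marginals), moments
anchored at a reference group summary at the 30% cutoff, a post/pre
change multiplier below 1 in the no-cancer group and 1.0 in the cancer
group, within-subject log-scale correlation 0.8, and a per-subject
exponential decay (e-folding 40%, lognormal jitter 0.15) expanding the
BPE measures over the cutoff grid so every subject's `|BPE|` is
non-increasing in the cutoff. `|BPE|` is derived from BPE% and the
subject's breast volume rather than drawn independently, so the
within-subject identities (`|BPE| <= |FGT|`,
`BPE% = 100 |BPE|/|Breast|`) hold by construction.

## Numerical choices and degenerate inputs

- FCM: deterministic quantile initialisation; a sample exactly at a
  centroid gets membership 1 (the zero-distance convention); the fuzzy
  objective is non-increasing by construction and asserted in tests.
- Ties at the hard-assignment boundary break toward the FGT class —
  conservative, since BPE is restricted to FGT anyway.
- Cutoff thresholds are inclusive (`>=`), so a cutoff of 0 counts all
  valid non-negative ratios.
- Zero-variance paired differences, single-class outcomes, empty masks,
  constant volumes and `pre = 0` records all return flagged results or
  informative errors rather than NaNs; pipeline stages name themselves
  in error messages.
- NIfTI headers store spacing and origin as 32-bit floats; round-trips
  are exact to that precision.

## Problem sizes in the test suite

Unit tests run on a half-size phantom (48 x 48 x 32) where segmentation
and registration behave identically but complete in seconds; the
acceptance tests run the full default phantom (96 x 96 x 64) through
the complete pipeline, two full-size registration recoveries, 1000-rep
null calibrations of the paired t and DeLong tests, and synthetic
cohorts up to n = (200, 30). These sizes were chosen so the whole suite
documents the method's behaviour at realistic scale while remaining
convenient to run routinely.

## Known limitations

- Plain 2-class FCM stands in for an atlas-aided segmentation: no
  spatial prior, so isolated dark fat voxels can be labelled FGT on
  noisy data (mitigated, on the phantom, by the intensity gap and the
  partial-volume margins).
- Rigid registration only; deformable motion and inter-time-point
  motion within the DCE series are not corrected.
- Bilateral scans are quantified as per-scan totals; no per-breast
  splitting.
- The pooled-LOOCV pessimism described above.
- The phantom's realism limits, listed in its section.
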