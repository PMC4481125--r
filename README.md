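# bpequant

Fully automated quantification of **background parenchymal enhancement
(BPE)** and **fibroglandular tissue (FGT)** from breast DCE-MRI, with
the paired pre/post cohort statistics used to evaluate these measures as
longitudinal biomarkers, and a ground-truthed digital phantom generator
for end-to-end validation.

## What it computes

On dynamic contrast-enhanced MRI, normal glandular tissue enhances
after gadolinium injection (the "background parenchymal enhancement").
`bpequant` replaces the visual BI-RADS grading of BPE with volumetric
measures. Per scan, with `|X|` in cm³:

```
FGT%  = 100 · |FGT| / |Breast|
R%    = 100 · I_sub / I_pre            (voxel-wise, inside the FGT)
|BPE| = volume of FGT voxels with R% ≥ R%_cutoff
BPE%  = 100 · |BPE| / |Breast|
```

The pipeline: breast segmentation on the non-fat-suppressed T1 volume
(air/fat half-height threshold from 3-class fuzzy C-means, hole
filling, edge-based chest-wall cut, morphological closing, largest
component) → FGT segmentation by 2-class fuzzy C-means (the dark class
is gland) → rigid registration of the T1 scan to the DCE pre-contrast
frame (mutual information, multi-resolution Nelder-Mead) → transfer of
the FGT mask onto the DCE grid → enhancement-ratio thresholding across
a cutoff grid (0–100% in steps of 10) for the early and delayed
subtraction images (SUB 1, SUB 3).

The statistics layer implements paired two-sided t tests with
Benjamini–Hochberg FDR correction, two-way ANOVA joint contrasts
(group × phase interaction), logistic regression on relative changes
`(post − pre)/pre` with ROC/AUC, DeLong's test for correlated AUCs, and
leave-one-out cross-validated AUCs, plus the p-value–versus-cutoff and
AUC-versus-cutoff profile sweeps.

## Worked example

Everything is testable without data: the phantom generator builds a
breast scene with known truth masks, known per-voxel enhancement
ratios, and a known rigid offset between the T1 and DCE frames.

```r
library(bpequant)

ph <- generate_phantom(phantom_spec(seed = 42))
q  <- quantify_scan(ph$t1, ph$study, sub_indices = c(1, 3))
summary(q, cutoff = 30)
#> |Breast| 94.69 cm^3, |FGT| 14.20 cm^3, FGT% 15.00%
#> At R%_cutoff = 30%:
#>   SUB 1: |BPE| 3.96 cm^3, BPE% 4.18%
#>   SUB 3: |BPE| 5.36 cm^3, BPE% 5.67%

true_bpe_cc(ph$truth, 1, 30); true_bpe_cc(ph$truth, 3, 30)
#> [1] 4.003
#> [1] 5.407

print(q$transform)   # truth: 3 deg about z, (2, -3, 1) mm
#> rigid_transform: rot (-0.093, 0.008, 3.118) deg, trans (2.060, -2.994, 1.040) mm
```

Reading: the recovered FGT fraction (15.00%) matches the phantom's
construction target; the measured enhancing volumes at the 30% cutoff
(3.96 / 5.36 cm³) sit within ~1% of the exact truth (4.003 / 5.407 cm³)
despite segmentation, a recovered ~3° / ~3.7 mm inter-scan motion, and
2% noise; and the delayed subtraction (SUB 3) shows more enhancing
volume than the early one (SUB 1), as longer uptake time demands.

Cohort level, on a synthetic 44 + 6 cohort whose no-cancer group
decreases post-intervention while the cancer group does not:

```r
co <- generate_cohort(cohort_spec(seed = 7))
analyze_cohort(co)
#> Cohort analysis at R%_cutoff = 30%
#>   FGTabs       p(no-cancer)=0.000392 [FDR 0.00235]  p(cancer)=0.975  ANOVA p=0.519  AUC=0.617
#>   FGTpct       p(no-cancer)=0.433 [FDR 0.433]  p(cancer)=0.791  ANOVA p=0.825  AUC=0.545
#>   BPEabs_SUB1  p(no-cancer)=0.0141 [FDR 0.0212]  p(cancer)=0.629  ANOVA p=0.678  AUC=0.356
#>   BPEpct_SUB1  p(no-cancer)=0.00336 [FDR 0.0101]  p(cancer)=0.14  ANOVA p=0.654  AUC=0.409
#>   BPEabs_SUB3  p(no-cancer)=0.00758 [FDR 0.0152]  p(cancer)=0.604  ANOVA p=0.488  AUC=0.723
#>   BPEpct_SUB3  p(no-cancer)=0.0423 [FDR 0.0507]  p(cancer)=0.727  ANOVA p=0.669  AUC=0.765
#>   Combined BPEpct_SUB1 + FGTabs: AUC = 0.636 (DeLong vs each: p = 0.089, 0.614)
```

The paired decrease is significant in the no-cancer group and
non-significant in the cancer group — the structure the generator
encodes. With only 6 cancer subjects the per-measure AUCs are highly
variable, which is the realistic behaviour at this cohort size.

## Command line

```sh
Rscript inst/cli/bpequant.R simulate phantom --seed 42 --out ./phantom
Rscript inst/cli/bpequant.R quantify --t1 phantom/t1.nii.gz \
    --pre phantom/pre.nii.gz \
    --post phantom/post1.nii.gz,phantom/post2.nii.gz,phantom/post3.nii.gz \
    --subs 1,3 --cutoffs 0:100:10 --out ./result
Rscript inst/cli/bpequant.R simulate cohort --seed 7 --out cohort.csv
Rscript inst/cli/bpequant.R cohort --table cohort.csv --out ./stats
```

Subcommands: `quantify`, `compare`, `cohort`, `simulate`. Every run
writes its resolved `config.json` and a timestamped `run.log` beside its
outputs; exit codes are 0 (success), 2 (input error), 3 (stage
failure).

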