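---
title: "Parametric feature maps and their statistical analysis: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parametric feature maps: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radiomaps)
```

## The map model

A parametric feature map replaces each small region of an image with a
radiomics feature value computed from the voxels in that region. `radiomaps`
tiles a 3D T2-weighted volume into non-overlapping rectangular cells of a
fixed physical size — 2 × 2 × 3 mm by default, the 3 mm axis matching a
typical T2w slice thickness — and computes 93 features per cell, yielding 93
spatially registered maps at the grid pitch. A lesion VOI drawn on the
original volume is transferred onto the grid and the mean map value over the
transferred cells is the lesion's value for that feature.

Three modelling commitments follow from this design:

* **No resampling.** Cells aggregate original-resolution voxels; the "2 mm"
  grid is a map pitch, not an interpolation target. This preserves the
  measured intensities and avoids an interpolation kernel choice that would
  otherwise silently shape every texture value. Each voxel is assigned to
  the cell containing its center, so cells partition the voxel lattice
  exactly; border cells may be smaller. A consequence worth noting: the grid
  extends only to the last *occupied* cell per axis — a trailing sliver of
  physical extent that contains no voxel center spawns no cell, so every
  cell holds at least one voxel.
* **Quasi-2D texture.** With 0.5 mm in-plane resolution and 3 mm slices, a
  2 × 2 × 3 mm cell is a single-slice 4 × 4 patch. Texture directions are
  therefore all Chebyshev-distance-1 offsets *that fit the patch*: four
  in-plane GLCM offset pairs and run directions for single-slice cells,
  expanding automatically to the full 13 3D directions when a cell spans
  multiple slices.
* **Small-sample conventions.** A 16-voxel patch routinely produces
  degenerate texture matrices. Every family returns its documented
  convention rather than an error: GLCM Correlation and MCC are 1 on a
  single-level matrix, NGTDM Coarseness is capped at 10^6, Busyness and
  Strength use 0/0 = 0, logarithms are base 2 with 0·log 0 = 0, and any
  patch without a valid neighbour pair (a single voxel) yields NaN for the
  texture families. First-order skewness and kurtosis of a constant patch
  are 0. Note that run and dependence entropies are nonzero even on constant
  patches — they mix in patch geometry (diagonal run lengths,
  border-truncated neighbourhoods), not only intensity variation.

## Feature definitions and discretization

The 93 features are the standard first-order (18), GLCM (24), GLDM (14),
GLRLM (16), GLSZM (16) and NGTDM (5) sets with IBSI-consistent formulas:
population variance, uncorrected Pearson kurtosis (a normal sample gives
≈ 3), energy with shift constant 0, total energy scaled by the physical
voxel volume, and percentile-based robust statistics (type-7 quantiles).
Entropy and uniformity are computed on the discretized histogram; all other
first-order features use raw intensities.

Gray levels are discretized per patch with a **fixed bin width of 25
intensity units from the patch minimum** (`level = floor((x − min)/w) + 1`).
A fixed bin count mode is available (`feature_settings(n_bins = ...)`).
Bin width 25 is the common radiomics default for T2w-scaled intensities; at
the phantom's background SD of 40 it produces roughly 3–8 occupied levels
per 16-voxel patch, enough to express texture without exploding matrix
sparsity. Per-patch (rather than per-volume) anchoring makes each cell's
texture self-referential; it also means maps are not sensitive to global
intensity offsets.

GLCM features are computed per offset on the symmetric, probability-
normalized matrix and averaged over offsets, run-length features per
direction and averaged; GLSZM zones use Chebyshev (26/8) connectivity; GLDM
dependence counts neighbours within `alpha = 0` gray levels, with border
voxels simply having fewer neighbours.

## The synthetic cohort

Real exams cannot ship with the package, so every downstream stage is
exercised on phantoms whose *statistical* structure matches the analysis
assumptions; no MR physics, bias fields or anatomy are attempted.

* **Cohort composition** mirrors the clinical cohort the analysis was
  designed around: 52 patients — 25/8 noPCa, 4/4 ciPCa and 8/3 csPCa over
  the peripheral/transition zones — with csPCa as the positive class and
  noPCa + ciPCa collapsed to non-csPCa.
* **Covariates.** PSA and prostate volume are log-normal (positive and
  right-skewed, as clinical IQRs suggest) with group medians 6 / 7.45 /
  9.7 ng/mL and 62 / 47 / 46 mL; the log-scale SDs (0.33, 0.30) were chosen
  once so the simulated IQRs roughly match the clinical ones. PSAD is
  PSA/volume by definition. Medians of log-normals are exact
  (`exp(meanlog)`), so simulated group medians converge to the configured
  values; a test checks within 10% at n = 2000 per group.
* **Images.** Background is white Gaussian noise smoothed with a 1-voxel
  in-plane Gaussian kernel and rescaled to mean 200 / SD 40 — a correlated
  field whose texture is stationary. The lesion is an ellipsoid (radii drawn
  from 4–12 mm by default; the clinical description gives no size
  distribution, only "strongly variable", so a uniform range was fixed once)
  whose voxels are transformed in place: every lesion is shifted down by
  `shift_all = 15`, csPCa lesions by an additional `shift_cs = 45` with
  local SD scaled by `1 + contrast_cs = 1.6`. This gives csPCa lesions a
  lower median, lower 10th percentile and minimum, and higher local
  contrast — a monotone, tunable class effect. With
  `lesion_effect_null()` the transform is the identity and the lesion is
  statistically invisible, which is the null configuration used for type-I
  checks.
* **Raters.** Rater 2's mask re-voxelizes a slightly perturbed ellipsoid
  (±0.5 mm center, ±5% radii) and flips each boundary voxel with
  probability 0.1. This keeps Dice > 0.5 by construction and leaves the
  extracted map means nearly identical, so the interrater ICC of the
  extracted features sits in the excellent range (median ≈ 0.99 across the
  93 features at the shipped problem sizes; a few weakly determined texture
  features can dip slightly below 0.9 when the phantom is small) —
  deliberately emulating the excellent-agreement regime the analysis is
  designed to report.

What passing tests on phantoms do **not** show: robustness to scanner
drift, bias fields, anatomy-correlated texture, or segmentation
disagreement beyond small boundary perturbations. The phantoms validate the
*computational pipeline and its statistical calibration*, not clinical
performance.

## The statistical pipeline

For each zone stratum (all lesions / PZ only / TZ only):

1. **Screening.** Two-sided Mann–Whitney U per feature, csPCa vs non-csPCa.
   Exact enumeration when `n1·n2 ≤ 400` and there are no ties, otherwise the
   normal approximation with tie and continuity correction. No multiplicity
   correction is applied across the 93 features by design (the analysis this
   package reproduces reports raw p-values); a Benjamini–Hochberg column can
   be switched on (`adjust_bh = TRUE`).
2. **Univariate models.** Unpenalized logistic regression of the label on
   the standardized feature, no upsampling. The ROC uses in-sample predicted
   probabilities with a fixed orientation (higher score = csPCa); since the
   link is monotone, the AUC equals the orientation-folded rank AUC
   `U/(n1·n2)` of the raw feature — a property the tests assert, which also
   ties the screening and modelling stages together. The operating point is
   the Youden maximum, ties broken toward higher sensitivity; sensitivity,
   specificity, PPV and NPV are reported there. Perfect separation is
   flagged (`separable`), not treated as an error, because the rank-based
   AUC remains well defined.
3. **Bivariate models.** Each screened feature (raw p < 0.05) is combined
   with PSAD in a ridge-penalized logistic model (`glmnet`, alpha = 0,
   lambda = 0.01 on standardized predictors; the penalty makes the refits
   stable under bootstrap resampling and upsampling at n ≈ 50). PSAD enters
   as a standardized continuous term or as a 0.15 / 0.20 (ng/mL)/cm³
   indicator. The minority class is upsampled with replacement to balance
   before fitting (deterministic per seed; the support of the minority
   class never changes, only multiplicities); scores and the apparent AUC
   are computed on the original patients. Standardization uses the
   population SD, so replicating every record leaves the fit unchanged.
4. **Bootstrap.** Patients are resampled with replacement, stratified by
   class so both classes appear in every replicate; the model is refitted
   (including a fresh upsampling draw) n = 1000 times by default. Odds
   ratios are `exp` of the mean coefficient, CIs are the 2.5/97.5
   percentiles, and the p-value is the two-sided sign share
   `2·min(#{b>0}+1, #{b<0}+1)/(B+1)` — the +1 terms give the natural
   1/(B+1) floor. The sign-share construction is one convention among
   several; it is monotone in the evidence and exactly reproducible.
5. **AUC ratings and comparisons.** AUCs are rated
   poor / acceptable / excellent / outstanding at 0.70 / 0.80 / 0.90
   (half-open bands, AUC below 0.5 reported as-is), correlated AUCs are
   compared with the paired DeLong test (self- or rank-identical
   comparisons return p = 1 by convention), and interrater reliability uses
   ICC(3,1) — two-way mixed, single rater, consistency,
   `(BMS − EMS)/(BMS + EMS)` for two raters — with the conventional
   poor / moderate / good / excellent bands at 0.5 / 0.75 / 0.9. Being a
   consistency coefficient it is invariant to an additive rater offset.
6. **Low-power flags.** A stratum with fewer than 2 events still yields a
   bivariate fit but is flagged `low_power`; with the default cohort's 3
   csPCa in the TZ this mirrors the caveat such strata deserve.

## Numerical and reproducibility choices

* Every random operation derives from one integer seed; per-case and
  per-replicate seeds are derived arithmetically (kept below 2^31), and the
  generator restores the caller's RNG state. The full
  simulate → maps → extract → stats pipeline is byte-reproducible, and the
  CLI is a thin dispatcher over the same functions, so both routes produce
  identical files.
* Probability-normalized matrices are checked to sum to 1 at 1e-9; texture
  matrices are validated against independent brute-force enumerations
  (pair scanning, run walking, recursive flood fill, neighbour counting) on
  random patches in the test suite.
* glmnet is run with a tightened convergence threshold (1e-10) so that
  replication invariance holds to ~1e-6.
* NIfTI I/O (via RNifti) stores masks as uint8 and maps/volumes as float32;
  map round trips are exact to float precision. World geometry is the
  simple axis-aligned case: voxel (i,j,k) centered at
  `origin + (i − 0.5)·spacing`.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on synthetic data at
reduced matrix sizes chosen to keep a full run comfortable on one CPU:
phantom volumes of 24–32 voxels in-plane (grid cells remain the full
2 × 2 × 3 mm), the default 52-patient cohort for image-based checks, 500
null simulations of n = 200 at 5 features for screening calibration, and
200 bootstrap-coverage runs on zero-effect cohorts of n = 150 (27% events) —
a size where percentile-bootstrap asymptotics hold; at n = 52 with 11
events the percentile CI's true coverage is ≈ 92%, a known small-sample
property of the construction rather than a defect. The coverage experiment
uses 1000 bootstrap replicates per run in the acceptance script and 400 in
the test suite; the bootstrap inside the full analysis keeps its n = 1000
default.

## Known limitations

* Feature values are not bit-compatible with any specific reference
  implementation: the discretization settings and intra-cell direction set
  are package choices (the corresponding clinical study does not state
  its own), so only structural and statistical properties are comparable.
* The phantom's texture model is additive-Gaussian; families driven by
  higher-order spatial structure (e.g. NGTDM Strength) discriminate classes
  only through the variance scaling.
* Apparent (in-sample) performance only, by design; no cross-validation or
  external validation is implemented.
* An optional overlapping sliding-window map mode is deliberately absent
  from the default path; cells are non-overlapping.
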