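---
title: "Predicting out-of-field recurrence from MRI radiomics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting out-of-field recurrence from MRI radiomics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

After definitive concurrent chemoradiotherapy (CCRT) for stage-IIB cervical
cancer, a substantial minority of patients relapse *outside* the irradiated
field — nodal or hematogenous spread that local dose escalation cannot
prevent, but that adjuvant systemic therapy might. The clinical question is
triage: which patients carry a high risk of out-of-field recurrence (OFR)
within three years of treatment start?

Para-aortic lymph node (PALN) involvement at diagnosis is the established
clinical risk factor, but it is an incomplete one: in the population this
package models, most OFR events (about 68%) arise in PALN-*negative*
patients. The hypothesis implemented here is that intratumoral texture on
pretreatment MRI — diffusion-weighted or T2-weighted — carries additional
signal, and that a sparse classifier built on wavelet-band texture features,
combined with PALN status, predicts OFR better than PALN status alone.

`ofradiomics` implements that analysis end to end: a synthetic phantom
cohort (there is no public imaging for this population), isotropic
resampling and intensity normalization, an undecimated 3D wavelet bank,
shape/histogram/gray-level texture features, survival-informed feature
selection, imbalance-weighted penalized classifiers, and cross-validated
ROC / NRI / IDI / concordance evaluation with Kaplan–Meier risk-group
comparison.

## The synthetic cohort

No patient images or accessions accompany the study population, so the
package ships a generator whose *statistical* structure matches what is
known about it, and every downstream claim is made against that phantom
cohort.

`cohort_config()` defaults encode the published contingency structure:

* 180 patients; PALN prevalence 21/180;
* P(OFR | PALN+) = 12/21 (57.1%), P(OFR | PALN−) = 26/159 (16.4%);
* 13 institutions, three of them (E, L, M) with more than 20 patients, two
  ("H", "J") with no OFR events — the pattern the institution-wise
  validation schemes must respect;
* OFR is an event only within 36 months of treatment start; event times are
  drawn uniform on (1, 36) months and event-free follow-up uniform on
  (36, 96). The uniform choice is deliberately non-informative: no time
  distribution is published, and nothing downstream uses the shape of the
  event-time density beyond the 36-month horizon.

Each patient gets an ellipsoidal tumor phantom (axis ratios drawn per
patient, rasterized volume matching the sampled tumor volume) on a
32×32×32 grid of 2 mm voxels. Interior intensity is a tumor base level of
100 plus a Gaussian random field; background sits at 20; white noise
(SD 2) is added everywhere. The outcome modulates the *texture* of the
field, not its mean: for patients who develop OFR the field's Gaussian
correlation length is multiplied by `1 + texture_effect_size` (base
0.7 voxels) and its standard deviation (base 15) by
`1 + 0.25 * texture_effect_size`. A smoothing-kernel manipulation was
chosen because it is exactly the kind of signal gray-level co-occurrence,
run-length, and size-zone statistics respond to, while remaining invisible
to first-order intensity summaries after normalization. Institution effects
are affine intensity distortions (log-normal scale, SD 0.08; additive
offset, SD 3) plus scanner noise (SD 2), derived deterministically from the
cohort seed.

Scale choices: tumor volumes are drawn log-uniformly over 3–30 ml so that
phantoms sit comfortably inside the 64 mm image extent; the published
cohort's volume range runs to 557 ml, which would require far larger grids
for no methodological gain. The screen thresholds that depend on that scale
(median volume 33 ml, median diameter 5.1 cm) are therefore configurable in
`prognostic_screen()`.

One seed governs the whole cohort; per-patient and per-institution streams
are derived by hashing `(seed, id)`, so enlarging a cohort does not
reshuffle existing patients.

What the phantom does *not* emulate: MRI physics (coil profiles, bias
fields, sequence contrast), anatomy, partial-volume effects at the tumor
boundary, segmentation variability, or any correlation between clinical
covariates and image content beyond the planted outcome effect. Passing
tests on this cohort therefore demonstrate that the pipeline's machinery is
correct and that it can find a planted texture signal through the
institution effects — not that real DWI texture predicts OFR.

## Image preprocessing

* **Resampling.** Image and mask are resampled to an isotropic 2 mm grid
  (trilinear for the image, nearest-neighbour for the mask), the working
  resolution of all feature definitions.
* **Normalization.** Two ROI-restricted intensity normalizations are
  provided — min–max to [0, 1] and z-score to mean 0, population SD 1.
  Both are exactly invariant to positive affine transforms of the raw
  intensities, which is the property that matters when scanners differ by
  gain and offset; the tests assert it exactly.
* **Discretization.** Texture matrices need gray levels: equal-width
  binning over the ROI range into 32 levels by default. The level count is
  a free parameter of every texture pipeline; 32 is the common middle
  ground for ROIs of a few thousand voxels (few enough voxels per level to
  resolve structure, enough to keep the matrices populated). Constant-ROI
  bands are flagged and fall back to documented degeneracy conventions
  rather than being imputed.

## The wavelet bank

A single-level *undecimated* (stationary) separable 3D wavelet transform
produces eight sub-bands labeled by the per-axis filter (L/H in axis order
x, y, z); together with the original image (band code `ROI`) they form the
nine-image bank every texture feature is computed on. The undecimated form
is what keeps all sub-bands on the original voxel grid, so one ROI mask
indexes all nine images without resampling.

Filter family: Coiflet-1, the filter used by the MATLAB radiomics toolkit
lineage this pipeline follows; Haar is available. Boundary handling is
mirror (symmetric) padding by default — small ROIs sit close to the crop
boundary and mirror padding avoids wrap-around ringing. A periodic mode is
also provided, under which the analysis/synthesis pair reconstructs the
input to machine precision (`wavelet_reconstruct()`, checked to 1e−8 in the
tests); with mirror padding reconstruction is exact away from the volume
boundary. The impulse response of every band is additionally checked
against a direct separable convolution oracle.

## Features and the registry

The published analysis names its features only by abbreviation
(`HHHRLV`, `HLHSZLGE`, …) and reports a total of 458 per sequence without
decomposing it. Rather than guess at that composition, the package makes
the feature set an explicit, auditable object: `feature_registry()` maps
each family to the statistics computed per band, and the default registry
computes 4 histogram + 3 GLCM + 3 GLRLM + 7 GLSZM + 2 NGTDM statistics per
band × 9 bands + 4 shape features = **175 features**, covering every
abbreviation that appears in the published feature lists. Bindings worth
stating because the abbreviations alone are ambiguous:

* `Energy` is the sum of squared ROI intensities (not histogram
  uniformity);
* `GCorrelation1` is the co-occurrence correlation of the
  direction-*merged* GLCM; `GCorrelation` averages the per-direction
  correlations — the two variants the published lists distinguish;
* GLCM/GLRLM pool the 13 unique 3D directions; GLSZM zones and NGTDM
  neighbourhoods use 26-connectivity;
* degeneracy conventions: constant ROI ⇒ correlation 0, busyness 0,
  skewness 0, all flagged;
* `SpheDisproportion` is surface area over that of the equal-volume sphere.
  Surface area comes from a marching-tetrahedra mesh of the box-smoothed
  mask indicator; the raw binary iso-surface overestimates curved surfaces
  by ~27% and does not converge, the smoothed mesh is within 2% for a
  rasterized ball at the working resolution.

Every texture statistic is verified exactly against independent brute-force
R oracles on randomized small volumes (pair enumeration, run walking, flood
fill, neighbourhood loops), and the pooled statistics are checked to be
invariant under 90° rotations, which exercise the direction set as a whole.

## Survival-guided feature selection

For the non-LASSO models the study protocol ranks features by prognostic
separation: split patients at the per-feature median, log-rank test on
OFR-free survival, order by significance, then greedily keep top features
while dropping any candidate whose |Pearson r| with an already-kept feature
exceeds 0.7, stopping at 10.

Two interpretation points, fixed here and controllable by argument:

* The protocol text says features were "arranged in order of decreasing
  p-value" and then the "top" features kept. Keeping the *largest* p-values
  would keep the least prognostic features, so the ranking is implemented
  by significance (ascending p) — the only reading under which the selector
  selects predictive features.
* Median ties go to the "low" group; Spearman correlation is available by
  flag.

A consistency property worth understanding: with three informative features
and seven decoys correlated at r ≈ 0.9, recovering the *originals* (not
their decoys) requires the original to out-rank every one of its own copies.
Detection only needs a log-rank z of ~4; reliable *ordering* against a
0.9-correlated copy needs the z-gap (about 10% of the z) to dominate the
noise between two highly correlated statistics, i.e. z ≈ 15–20. The
recovery test therefore runs at 2000 patients with a strong planted hazard,
where recovery is essentially certain, rather than at a size where the
property cannot hold for any effect size.

## Models

Four families, all exposed behind one `predict_probability()` interface,
with the 36-month OFR indicator as outcome:

* **Penalized logistic (LASSO / Ridge)** via glmnet on features
  standardized with training-fold means/SDs. Class imbalance is corrected
  by balanced loss weights `w_c = n / (2 n_c)` (so each class contributes
  half the weighted loss; with the study's 38/142 split,
  `w_pos ≈ 2.37`, `w_neg ≈ 0.63`). The penalty is tuned by leave-one-out
  *weighted log-likelihood* over a 50-point log-spaced grid on
  [1e−4, 1e+2]; ties go to the larger (more regularized) λ. The LOO
  criterion matches the weighted training loss — accuracy-based tuning
  would be inconsistent with it. Degenerate training subsets (e.g. a fold
  with no PALN-positive patients in the clinical design) fall back to the
  intercept-only model predicting the weighted base rate.
* **Ridge for the clinical design** (the protocol's choice): with PALN as
  the single covariate this is a shrunken 2×2 model; the design matrix is
  padded with an inert zero column only to satisfy the solver's interface,
  which provably leaves the solution unchanged.
* **Gaussian naive Bayes** with class priors taken from the *weighted*
  class frequencies (uniform under balanced weights) and per-class
  variances floored at 1e−8 (flagged); cross-checked against e1071 where
  the conventions coincide.
* **Random forest** with Gini splits, 500 trees, √p features per split,
  fully seeded.

Feature standardization, feature selection and model fitting all happen
inside each training fold only. The test suite includes a direct
no-leakage check: shuffling the labels of a test fold leaves that fold's
fitted coefficients bit-identical.

## Survival machinery

Kaplan–Meier estimation, the two-group log-rank test and Cox
proportional-hazards fits are delegated to the survival package (Breslow
ties by default, Efron by flag) and re-exposed in the package's own
containers. Conventions: OFR events are defined only within the 36-month
horizon; later recurrences are censored at 36 months; deaths without OFR
are censored at last follow-up (the protocol is silent; censoring is the
default that keeps OFR-free survival interpretable). Three-year OFR-free
percentages are read off the curve at month 36. The calibration suite
checks KM against the empirical survivor function, log-rank type-I error
against its nominal level over 2000 null replicates, and Cox recovery of a
known hazard ratio.

`prognostic_screen()` reproduces the classic prognostic-factor table:
per-variable dichotomization (age 56, diameter 5.1 cm, volume 33 ml,
whole-pelvis dose 50 Gy, point-A dose 24.2 Gy, nodal statuses), univariate
log-rank plus one multivariate Cox fit, and marks the variables significant
in both — the rule that singles out PALN as the clinical predictor.

## Evaluation

* **Cross-validation**: label-stratified 5-fold (the primary scheme);
  leave-one-institution-out; and a three-large-institution holdout in which
  the held-out institution is scored by averaging the probabilities of the
  five models fitted inside the training institutions. Institutions without
  events are never eligible as test sets.
* **ROC/AUC** by the rank (Mann–Whitney) formulation with midrank tie
  handling, cross-checked against pROC. Both the per-fold mean ± SD AUC and
  the pooled out-of-fold ROC are reported — they answer different
  questions and the published figures show both.
* **NRI/IDI**: the *continuous* (category-free) variants, since no risk
  categories are published. Sign convention: new minus reference, positive
  when the combined model improves on the clinical one. The published
  comparison reports negative NRI/IDI alongside a higher combined AUC;
  whatever reference direction produced that sign, this package documents
  its own convention and does not attempt to reproduce the sign. Confidence
  intervals are percentile bootstrap (2000 seeded resamples) with a
  normal-approximation p-value.
* **C-index**: Harrell's concordance of the out-of-fold probability against
  OFR-free survival time, ties 0.5, checked against hand pair-enumeration.
* **Risk groups**: patients split at predicted probability 0.5, KM per
  group, log-rank comparison.

## Problem sizes and numerical choices

The test and acceptance workloads use: 200-patient cohorts on 32³ grids for
the end-to-end properties (null-cohort AUC ≈ 0.5, planted-signal AUC >
0.85 at `texture_effect_size = 2.5`, combined-beats-clinical in paired
replicates); 2000-patient tabular cohorts for selector consistency; 2000
replicates for test calibration. These sizes were chosen as the smallest at
which the corresponding asymptotic properties are comfortably expressed.
Other numerical conventions: Newton convergence for Cox at gradient norm
1e−9 (cap |β| ≤ 15 with a monotone-likelihood flag), probability clamping
at 1e−12 inside the LOO log-likelihood, equal-width discretization
invariant under affine maps by construction.

## Limitations

The phantom cohort is a machinery test bed, not evidence about cervical
cancer; absolute AUCs on it are not comparable to values obtained on
patient data. Only single-sequence analysis is implemented (run the
pipeline twice for DWI-like and T2-like settings); dosimetric covariates
enter only as screen variables; and the feature registry, while covering
every published abbreviation, is an explicit reconstruction rather than a
replica of the original 458-feature set.
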