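# ofradiomics

Prediction of out-of-field recurrence (OFR) of locally advanced cervical
cancer after concurrent chemoradiotherapy, from pretreatment MRI radiomics
combined with para-aortic lymph node (PALN) status.

## Who this is for

Radiation-oncology and imaging researchers who want a tested, reproducible
reference implementation of the classic single-sequence radiomics survival
pipeline: segmentation-mask-driven feature extraction over a 3D wavelet
bank, survival-informed feature selection, imbalance-weighted sparse
classification, and cross-validated model comparison — exercised end to end
on a synthetic phantom cohort, because no public imaging exists for this
population.

## The model

Patients are labeled by the 36-month OFR indicator. For patient *i* with
feature vector *x<sub>i</sub>* (standardized within the training fold), the
risk model is penalized logistic regression with class-balanced loss
weights *w<sub>c</sub> = n / (2 n<sub>c</sub>)*:

    min_(b0, b)  - sum_i w_{y_i} [ y_i log p_i + (1 - y_i) log(1 - p_i) ]
                 + lambda * P(b),        p_i = logit^{-1}(b0 + b' x_i)

with *P* the L1 (LASSO, radiomics and combined designs) or L2 (Ridge,
clinical design) penalty, and lambda chosen by leave-one-out weighted
log-likelihood inside the training fold. Features are computed per wavelet
band (undecimated coif1 transform; band codes `LLL` … `HHH`, plus `ROI` for
the original image) and comprise histogram moments, GLCM/GLRLM/GLSZM/NGTDM
texture statistics and mesh-based shape descriptors, e.g. `HHHRLV` = the
run-length variance of the HHH band. Models are compared by
cross-validated ROC/AUC, continuous NRI and IDI, Harrell's C-index and
Kaplan-Meier risk-group separation; clinical covariates are screened with
log-rank tests and a multivariate Cox model.

## Worked example

```r
library(ofradiomics)

# a 60-patient phantom cohort with a strong planted texture signal
cfg    <- cohort_config(n_patients = 60, texture_effect_size = 2.5, seed = 11)
cohort <- simulate_cohort(cfg)
feats  <- extract_cohort_features(cohort)       # 175 features per patient

ex <- run_experiment(feats, cohort$records, seed = 3)
ex
#> Out-of-field recurrence prediction experiment
#> <clinical_only / ridge, fivefold> AUC 0.733 +/- 0.070 (pooled 0.691)
#>   mean accuracy 0.885, sensitivity 0.467, specificity 1.000
#> <radiomics_only / lasso, fivefold> AUC 1.000 +/- 0.000 (pooled 1.000)
#>   mean accuracy 1.000, sensitivity 1.000, specificity 1.000
#> <combined / lasso, fivefold> AUC 1.000 +/- 0.000 (pooled 1.000)
#>   mean accuracy 1.000, sensitivity 1.000, specificity 1.000
#> combined vs clinical: NRI 2.000 (p=2e-16), IDI 0.701 (p=1.28e-14)
#> C-index clinical 0.689, combined 0.943
```

Reading this: PALN alone discriminates moderately (AUC 0.73); the planted
texture signal is fully recoverable from the images (radiomics AUC 1.0 at
this effect size), so the combined model reclassifies every patient in the
right direction (continuous NRI at its maximum of 2) and lifts the C-index
from 0.69 to 0.94. On a *label-free* cohort (`texture_effect_size = 0`) the
radiomics AUC drops to chance — that calibration is part of the test suite.

Clinical screening and the full pipeline:

```r
prognostic_screen(cohort$records)      # log-rank + Cox table, flags PALN
run_pipeline(list(seed = 1), "out")    # simulate -> extract -> evaluate -> report
```

`run_pipeline()` writes `features.csv`, `selection.json`, `summary.json`
and ROC/KM figures; `inst/cli/ofradiomics.R` exposes the same stages as
shell subcommands (`simulate`, `extract`, `select`, `evaluate`, `run`).

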