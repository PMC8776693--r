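Package: ofradiomics
Title: MRI Radiomics Prediction of Out-of-Field Recurrence After
    Chemoradiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end pipeline for predicting out-of-field recurrence of
    locally advanced cervical cancer after concurrent chemoradiotherapy from
    pretreatment MRI radiomics combined with para-aortic lymph node status.
    Provides a synthetic phantom cohort generator with institution-level
    intensity effects, isotropic resampling and intensity normalization of
    tumor volumes, an undecimated 3D wavelet filter bank, shape, histogram
    and gray-level texture features (GLCM, GLRLM, GLSZM, NGTDM),
    survival-informed feature selection, imbalance-weighted penalized
    classifiers with leave-one-out hyperparameter tuning, Kaplan-Meier,
    log-rank and Cox proportional-hazards screening, and cross-validated
    ROC, NRI, IDI and concordance-index model comparison.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    grDevices,
    graphics,
    jsonlite,
    randomForest,
    Rcpp,
    RNifti,
    stats,
    survival,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    e1071,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
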