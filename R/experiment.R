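#' Cross-validated evaluation of one model design
#'
#' Trains and evaluates one model family on one design under a
#' cross-validation scheme, with feature selection and standardization
#' re-run inside every training fold so no information leaks into the test
#' folds. For the LASSO the embedded selection operates on all features; for
#' the other families the survival-based selector ([km_rank_features()] +
#' [prune_and_take()]) picks the top features within each training fold.
#' Under the `three_institution_holdout` scheme the held-out institution is
#' scored by averaging the probabilities of the five nested fold models.
#'
#' @param features Radiomics feature table (`NULL` allowed for
#'   `clinical_only`).
#' @param records Clinical table.
#' @param design `"clinical_only"`, `"radiomics_only"` or `"combined"`.
#' @param family `"lasso"`, `"ridge"`, `"naive_bayes"` or `"random_forest"`.
#' @param scheme A `cv_scheme` from [assign_folds()].
#' @param selection `"auto"` (embedded for lasso, survival ranking
#'   otherwise), `"km_prune"`, or `"none"`.
#' @param select_k,corr_threshold Selector parameters (top 10, |r| > 0.7).
#' @param class_weighting Imbalance correction (default TRUE).
#' @param lambda_grid Penalty grid for the penalized families.
#' @param threshold Decision threshold for the reported metrics.
#' @return Object of class `model_eval`: out-of-fold probabilities and
#'   indices, per-fold and pooled AUC/metrics, the pooled ROC and the
#'   per-fold fitted models and selected features.
#' @export
evaluate_model <- function(features, records, design, family = "lasso",
                           scheme, selection = "auto", select_k = 10,
                           corr_threshold = 0.7, class_weighting = TRUE,
                           lambda_grid = default_lambda_grid(),
                           threshold = 0.5) {
  family <- match.arg(family, c("lasso", "ridge", "naive_bayes",
                                "random_forest"))
  selection <- match.arg(selection, c("auto", "km_prune", "none"))
  if (selection == "auto")
    selection <- if (family == "lasso") "none" else "km_prune"
  use_radiomics <- design != "clinical_only"
  fold_auc <- c()
  fold_metrics <- list()
  fold_models <- list()
  fold_selected <- list()
  oof_prob <- rep(NA_real_, nrow(records))
  tested <- integer(0)

  fit_one <- function(train_idx) {
    rec_tr <- records[train_idx, , drop = FALSE]
    sel <- NULL
    if (use_radiomics && selection == "km_prune") {
      ranked <- km_rank_features(features, rec_tr)
      sel <- prune_and_take(ranked, feature_subset(features, rec_tr),
                            threshold = corr_threshold, k = select_k)$kept
    }
    dz <- make_design(rec_tr, features, design, feature_names = sel)
    model <- switch(family,
      lasso = fit_penalized(dz$X, dz$y, "lasso", class_weighting,
                            lambda_grid),
      ridge = fit_penalized(dz$X, dz$y, "ridge", class_weighting,
                            lambda_grid),
      naive_bayes = fit_naive_bayes(dz$X, dz$y, class_weighting),
      random_forest = fit_random_forest(dz$X, dz$y, class_weighting,
                                        seed = derive_seed(scheme$seed,
                                                           "rf")))
    list(model = model, selected = sel)
  }
  predict_split <- function(fit, test_idx) {
    rec_te <- records[test_idx, , drop = FALSE]
    dz <- make_design(rec_te, features, design, feature_names = fit$selected)
    predict_probability(fit$model, dz$X)
  }

  for (sp in scheme$splits) {
    if (!is.null(sp$inner_folds)) {
      probs <- matrix(NA_real_, length(sp$test), 5)
      inner_models <- list()
      for (f in sort(unique(sp$inner_folds))) {
        fit <- fit_one(sp$train[sp$inner_folds != f])
        probs[, f] <- predict_split(fit, sp$test)
        inner_models[[f]] <- fit
      }
      p_test <- rowMeans(probs)
      fit <- list(model = lapply(inner_models, `[[`, "model"),
                  selected = NULL)
    } else {
      fit <- fit_one(sp$train)
      p_test <- predict_split(fit, sp$test)
    }
    oof_prob[sp$test] <- p_test
    tested <- c(tested, sp$test)
    y_test <- as.integer(records$ofr_event[sp$test])
    if (length(unique(y_test)) == 2) {
      fold_auc[sp$name] <- roc_and_auc(p_test, y_test)$auc
      fold_metrics[[sp$name]] <- threshold_metrics(p_test, y_test, threshold)
    }
    fold_models[[sp$name]] <- fit$model
    fold_selected[[sp$name]] <- fit$selected
  }
  tested <- sort(unique(tested))
  y_pooled <- as.integer(records$ofr_event[tested])
  pooled_roc <- roc_and_auc(oof_prob[tested], y_pooled)
  structure(list(
    design = design, family = family, scheme_kind = scheme$kind,
    fold_auc = fold_auc, mean_auc = mean(fold_auc), sd_auc = sd(fold_auc),
    pooled_auc = pooled_roc$auc, roc = pooled_roc,
    metrics = list(per_fold = fold_metrics,
                   mean = if (length(fold_metrics))
                     colMeans(do.call(rbind, fold_metrics), na.rm = TRUE)
                   else c(accuracy = NA_real_, sensitivity = NA_real_,
                          specificity = NA_real_),
                   pooled = threshold_metrics(oof_prob[tested], y_pooled,
                                              threshold)),
    oof_prob = oof_prob, tested = tested,
    fold_models = fold_models, fold_selected = fold_selected),
    class = "model_eval")
}

feature_subset <- function(features, records) {
  if (is.null(features)) return(NULL)
  idx <- match(records$patient_id, features$patient_id)
  features[idx, , drop = FALSE]
}

#' Run the full modelling experiment on a cohort
#'
#' Evaluates the clinical-only, radiomics-only and combined designs under a
#' shared cross-validation scheme (so comparisons are paired), then compares
#' the combined model against the clinical reference with continuous NRI,
#' IDI and Harrell's C-index, and splits patients into predicted-risk groups
#' at probability 0.5 for a Kaplan-Meier comparison.
#'
#' @param features Radiomics feature table.
#' @param records Clinical table.
#' @param designs Subset of the three designs (default all).
#' @param families Named family per design; defaults follow the study
#'   protocol (Ridge for the clinical design, LASSO otherwise).
#' @param scheme_kind,n_folds,seed Passed to [assign_folds()].
#' @param n_boot Bootstrap resamples for NRI/IDI.
#' @param ... Further arguments for [evaluate_model()].
#' @return Object of class `ofr_experiment`: per-design `model_eval`s,
#'   `comparison` (NRI, IDI, C-indexes), `risk_groups`, and a reproducibility
#'   `manifest`.
#' @export
run_experiment <- function(features, records,
                           designs = c("clinical_only", "radiomics_only",
                                       "combined"),
                           families = c(clinical_only = "ridge",
                                        radiomics_only = "lasso",
                                        combined = "lasso"),
                           scheme_kind = "fivefold", n_folds = 5L,
                           seed = 1L, n_boot = 2000, ...) {
  scheme <- assign_folds(records, scheme_kind, n_folds = n_folds, seed = seed)
  reports <- list()
  for (d in designs)
    reports[[d]] <- evaluate_model(features, records, d,
                                   family = families[[d]], scheme = scheme,
                                   ...)
  comparison <- NULL
  risk_groups <- NULL
  if (all(c("clinical_only", "combined") %in% designs)) {
    idx <- intersect(reports$clinical_only$tested, reports$combined$tested)
    p_ref <- reports$clinical_only$oof_prob[idx]
    p_new <- reports$combined$oof_prob[idx]
    y <- records$ofr_event[idx]
    tm <- records$time_months[idx]
    comparison <- list(
      nri = nri(p_ref, p_new, y, n_boot = n_boot,
                seed = derive_seed(seed, "nri")),
      idi = idi(p_ref, p_new, y, n_boot = n_boot,
                seed = derive_seed(seed, "idi")),
      c_index_clinical = c_index(p_ref, tm, y),
      c_index_combined = c_index(p_new, tm, y))
    risk_groups <- list(
      clinical_only = risk_group_km(p_ref, records[idx, , drop = FALSE]),
      combined = risk_group_km(p_new, records[idx, , drop = FALSE]))
  }
  structure(list(designs = reports, comparison = comparison,
                 risk_groups = risk_groups,
                 manifest = list(seed = seed, scheme = scheme_kind,
                                 n_folds = n_folds,
                                 n_patients = nrow(records),
                                 n_features = if (is.null(features)) 0
                                 else ncol(features) - 1,
                                 families = as.list(families[designs]))),
            class = "ofr_experiment")
}

#' @export
print.model_eval <- function(x, ...) {
  cat(sprintf("<%s / %s, %s> AUC %.3f +/- %.3f (pooled %.3f)\n",
              x$design, x$family, x$scheme_kind, x$mean_auc,
              ifelse(is.na(x$sd_auc), 0, x$sd_auc), x$pooled_auc))
  m <- x$metrics$mean
  cat(sprintf("  mean accuracy %.3f, sensitivity %.3f, specificity %.3f\n",
              m["accuracy"], m["sensitivity"], m["specificity"]))
  invisible(x)
}

#' @export
print.ofr_experiment <- function(x, ...) {
  cat("Out-of-field recurrence prediction experiment\n")
  for (r in x$designs) print(r)
  if (!is.null(x$comparison)) {
    cat(sprintf("combined vs clinical: NRI %.3f (p=%.3g), IDI %.3f (p=%.3g)\n",
                x$comparison$nri$estimate, x$comparison$nri$p,
                x$comparison$idi$estimate, x$comparison$idi$p))
    cat(sprintf("C-index clinical %.3f, combined %.3f\n",
                x$comparison$c_index_clinical, x$comparison$c_index_combined))
  }
  invisible(x)
}
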