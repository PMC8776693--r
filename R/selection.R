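#' Rank features by median-split survival separation
#'
#' For each feature, patients are split at the per-feature median (values
#' equal to the median go to the "low" group), the two groups are compared
#' with a log-rank test on OFR-free survival, and features are ordered by
#' significance (smallest p first, ties broken by feature name). Features
#' that cannot be split (constant, or fewer than 2 patients per group) are
#' placed last with p = 1 and flagged.
#'
#' @param features Feature table (`data.frame` with `patient_id` plus
#'   numeric feature columns, or a plain numeric data.frame/matrix).
#' @param records Clinical table aligned with `features` (matched on
#'   `patient_id` when both carry it).
#' @return `data.frame` of class `km_ranking` with columns `feature`, `p`,
#'   `rankable`, in rank order.
#' @export
km_rank_features <- function(features, records) {
  X <- feature_matrix(features, records)
  times <- records$time_months
  events <- records$ofr_event
  ps <- vapply(colnames(X), function(nm) {
    v <- X[, nm]
    hi <- v > median(v)
    if (sum(hi) < 2 || sum(!hi) < 2) return(NA_real_)
    logrank_test(times, events, hi)$p
  }, numeric(1))
  rankable <- !is.na(ps)
  ps[!rankable] <- 1
  ord <- order(ps, colnames(X))
  structure(data.frame(feature = colnames(X)[ord], p = ps[ord],
                       rankable = rankable[ord], stringsAsFactors = FALSE),
            class = c("km_ranking", "data.frame"))
}

# align a feature table with the clinical records and return the numeric
# feature matrix (patients in record order)
feature_matrix <- function(features, records = NULL) {
  df <- as.data.frame(features)
  if ("patient_id" %in% names(df)) {
    if (!is.null(records) && "patient_id" %in% names(records)) {
      idx <- match(records$patient_id, df$patient_id)
      if (anyNA(idx))
        stop_config("feature table is missing patient(s): %s",
                    paste(records$patient_id[is.na(idx)], collapse = ", "))
      df <- df[idx, , drop = FALSE]
    }
    df$patient_id <- NULL
  }
  as.matrix(df)
}

#' Correlation-pruned top-k selection
#'
#' Greedy pass over the ranked features: a candidate is dropped when its
#' absolute correlation with any already-kept feature exceeds `threshold`;
#' the pass stops after `k` features are kept or the list is exhausted.
#'
#' @param ranked A `km_ranking` from [km_rank_features()] (or any data.frame
#'   with a `feature` column in rank order).
#' @param features Feature table the correlations are computed on.
#' @param threshold Absolute correlation above which a candidate is dropped
#'   (default 0.7).
#' @param k Maximum number of features to keep (default 10).
#' @param method Correlation type, `"pearson"` (default) or `"spearman"`.
#' @return List of class `selection_result`: `kept` (ordered names),
#'   `dropped_for_correlation` (data.frame name/partner/abs_r), `ranked`.
#' @export
prune_and_take <- function(ranked, features, threshold = 0.7, k = 10,
                           method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (nrow(ranked) == 0) stop_config("prune_and_take: empty ranking")
  X <- feature_matrix(features)
  kept <- character(0)
  dropped <- list()
  for (nm in ranked$feature) {
    if (length(kept) >= k) break
    if (length(kept)) {
      r <- abs(suppressWarnings(
        cor(X[, nm], X[, kept, drop = FALSE], method = method)))
      r[is.na(r)] <- 0  # constant features correlate with nothing
      if (any(r > threshold)) {
        j <- which.max(r)
        dropped[[nm]] <- data.frame(name = nm, partner = kept[j],
                                    abs_r = r[j], stringsAsFactors = FALSE)
        next
      }
    }
    kept <- c(kept, nm)
  }
  structure(list(kept = kept,
                 dropped_for_correlation = if (length(dropped))
                   do.call(rbind, c(dropped, list(make.row.names = FALSE)))
                 else data.frame(name = character(0), partner = character(0),
                                 abs_r = numeric(0)),
                 ranked = ranked),
            class = "selection_result")
}

#' Features selected by a fitted sparse model
#'
#' Names of the features with nonzero coefficients in a fitted penalized
#' model (the LASSO's embedded selection).
#'
#' @param model A `penalized_fit` from [fit_penalized()].
#' @return Character vector of feature names.
#' @export
lasso_selected_features <- function(model) {
  if (!inherits(model, "penalized_fit"))
    stop_config("lasso_selected_features: expected a fitted penalized model")
  cf <- model$coefficients
  names(cf)[cf != 0]
}

#' Cross-fold selection stability
#'
#' How many cross-validation folds selected each feature, mirroring the
#' published "selected four times / five times" stability report.
#'
#' @param fold_models List of per-fold `penalized_fit` models (e.g.
#'   `report$fold_models` from [evaluate_model()]).
#' @return Named integer vector, decreasing; bounded by the fold count.
#' @export
selection_stability <- function(fold_models) {
  tab <- table(unlist(lapply(fold_models, lasso_selected_features)))
  sort(setNames(as.integer(tab), names(tab)), decreasing = TRUE)
}
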