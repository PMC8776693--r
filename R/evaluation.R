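#' Cross-validation fold assignment
#'
#' Three schemes mirroring the study's validation designs:
#' * `fivefold` — label-stratified random partition into `n_folds` folds;
#' * `leave_one_institution_out` — one split per institution that has at
#'   least one event and one non-event; institutions with zero events never
#'   appear as test data;
#' * `three_institution_holdout` — one split per institution with more than
#'   20 patients; the training part carries a nested label-stratified 5-fold
#'   assignment, and the test prediction is the average of the five
#'   fold-models' probabilities.
#'
#' @param records Clinical table with `ofr_event` (and `institution` for the
#'   institution schemes).
#' @param kind Scheme kind.
#' @param n_folds Number of folds for `fivefold` (default 5).
#' @param seed Integer seed; identical seeds give identical assignments.
#' @param min_test_size Patient threshold for `three_institution_holdout`
#'   (default 20, "more than").
#' @return Object of class `cv_scheme`: list with `kind` and `splits`, each
#'   split a list with `name`, `train`, `test` (row indices) and optionally
#'   `inner_folds`.
#' @export
assign_folds <- function(records, kind = c("fivefold",
                                           "leave_one_institution_out",
                                           "three_institution_holdout"),
                         n_folds = 5L, seed = 1L, min_test_size = 20L) {
  kind <- match.arg(kind)
  y <- as.integer(as.logical(records$ofr_event))
  n <- length(y)
  if (kind == "fivefold") {
    fold <- withr::with_seed(seed, stratified_folds(y, n_folds))
    splits <- lapply(seq_len(n_folds), function(f) {
      list(name = sprintf("fold%d", f), train = which(fold != f),
           test = which(fold == f))
    })
  } else {
    inst <- as.character(records$institution)
    ev_by_inst <- tapply(y, inst, sum)
    n_by_inst <- table(inst)
    eligible <- names(ev_by_inst)[ev_by_inst > 0 &
                                    n_by_inst[names(ev_by_inst)] > ev_by_inst]
    if (kind == "three_institution_holdout")
      eligible <- intersect(eligible,
                            names(n_by_inst)[n_by_inst > min_test_size])
    if (!length(eligible))
      stop_config("assign_folds: no eligible test institution")
    splits <- lapply(eligible, function(id) {
      test <- which(inst == id)
      train <- which(inst != id)
      sp <- list(name = id, train = train, test = test)
      if (kind == "three_institution_holdout") {
        inner <- withr::with_seed(derive_seed(seed, paste0("inner:", id)),
                                  stratified_folds(y[train], 5L))
        sp$inner_folds <- inner
      }
      sp
    })
  }
  structure(list(kind = kind, splits = splits, seed = seed), class = "cv_scheme")
}

# label-stratified fold assignment; re-deals (up to 20 times) if any training
# set misses a class
stratified_folds <- function(y, n_folds, max_retry = 20L) {
  n <- length(y)
  for (attempt in seq_len(max_retry)) {
    fold <- integer(n)
    for (cls in unique(y)) {
      idx <- which(y == cls)
      fold[idx] <- (sample.int(length(idx)) %% n_folds) + 1L
    }
    ok <- all(vapply(seq_len(n_folds), function(f)
      length(unique(y[fold != f])) == length(unique(y)), logical(1)))
    if (ok) return(fold)
  }
  stop_config("stratified_folds: could not build folds with both classes in every training set")
}

#' ROC curve and AUC
#'
#' AUC by the rank (Mann-Whitney) formulation with tie correction; the curve
#' by a threshold sweep over the observed scores.
#'
#' @param probabilities Numeric risk scores.
#' @param labels Binary outcome.
#' @return List of class `roc_curve` with `curve` (data.frame `fpr`, `tpr`,
#'   `threshold`) and `auc`.
#' @export
roc_and_auc <- function(probabilities, labels) {
  y <- as.integer(as.logical(labels))
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    stop_config("roc_and_auc: both classes must be present")
  r <- rank(probabilities)  # midranks handle ties
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(probabilities), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(probabilities[y == 1] >= t), 0)
  fpr <- vapply(thr, function(t) mean(probabilities[y == 0] >= t), 0)
  curve <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                      tpr = c(0, tpr))
  structure(list(curve = curve, auc = auc), class = "roc_curve")
}

#' Confusion-matrix metrics at a probability threshold
#'
#' Accuracy, sensitivity and specificity of the dichotomized probabilities
#' (predicted positive when probability > threshold, matching the risk-group
#' split at 0.5). Metrics with an empty denominator are `NA`.
#'
#' @param probabilities Numeric probabilities.
#' @param labels Binary outcome.
#' @param threshold Decision threshold (default 0.5).
#' @return Named vector `accuracy`, `sensitivity`, `specificity`.
#' @export
threshold_metrics <- function(probabilities, labels, threshold = 0.5) {
  y <- as.integer(as.logical(labels))
  pred <- as.integer(probabilities > threshold)
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  c(accuracy = mean(pred == y),
    sensitivity = safe(sum(pred == 1 & y == 1), sum(y == 1)),
    specificity = safe(sum(pred == 0 & y == 0), sum(y == 0)))
}

#' Continuous NRI and IDI
#'
#' Category-free net reclassification improvement,
#' `NRI = [P(up|event) - P(down|event)] - [P(up|non-event) - P(down|non-event)]`,
#' and integrated discrimination improvement,
#' `IDI = (mean(p_new) - mean(p_ref) | events) - (mean(p_new) - mean(p_ref) | non-events)`,
#' of a new model against a reference on the same patients (positive when
#' the new model improves on the reference). Percentile confidence interval
#' and a normal-approximation p-value come from a seeded bootstrap.
#'
#' @param p_ref,p_new Probability vectors of the reference and new model.
#' @param labels Binary outcome.
#' @param n_boot Bootstrap resamples (default 2000).
#' @param conf_level CI level (default 0.95).
#' @param seed Bootstrap seed.
#' @return For `nri()`/`idi()`: list with `estimate`, `ci`, `p`.
#' @export
nri <- function(p_ref, p_new, labels, n_boot = 2000, conf_level = 0.95,
                seed = 1L) {
  reclass_stat(p_ref, p_new, labels, nri_estimate, n_boot, conf_level, seed)
}

#' @rdname nri
#' @export
idi <- function(p_ref, p_new, labels, n_boot = 2000, conf_level = 0.95,
                seed = 1L) {
  reclass_stat(p_ref, p_new, labels, idi_estimate, n_boot, conf_level, seed)
}

nri_estimate <- function(p_ref, p_new, y) {
  up <- p_new > p_ref
  down <- p_new < p_ref
  (mean(up[y == 1]) - mean(down[y == 1])) -
    (mean(up[y == 0]) - mean(down[y == 0]))
}

idi_estimate <- function(p_ref, p_new, y) {
  d <- p_new - p_ref
  mean(d[y == 1]) - mean(d[y == 0])
}

reclass_stat <- function(p_ref, p_new, labels, stat_fn, n_boot, conf_level,
                         seed) {
  if (length(p_ref) != length(p_new))
    stop_config("reference and new probabilities must cover the same patients")
  y <- as.integer(as.logical(labels))
  est <- stat_fn(p_ref, p_new, y)
  boots <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(length(y), replace = TRUE)
      if (length(unique(y[idx])) < 2) return(NA_real_)
      stat_fn(p_ref[idx], p_new[idx], y[idx])
    }, numeric(1))
  })
  boots <- boots[!is.na(boots)]
  alpha <- 1 - conf_level
  se <- sd(boots)
  p <- if (!is.finite(se) || se == 0) {
    if (est == 0) 1 else 2e-16  # statistic identical in every resample
  } else 2 * pnorm(-abs(est / se))
  list(estimate = est,
       ci = unname(quantile(boots, c(alpha / 2, 1 - alpha / 2))),
       p = p, n_boot = length(boots))
}

#' Harrell's concordance index
#'
#' Fraction of comparable patient pairs whose risk ordering matches the
#' outcome ordering, ties counted 0.5, via [survival::concordance] with
#' higher scores treated as higher risk.
#'
#' @param scores Risk scores (e.g. predicted probabilities).
#' @param times,events Survival data.
#' @return Concordance in `[0, 1]`.
#' @export
c_index <- function(scores, times, events) {
  ev <- as.integer(as.logical(events))
  if (sum(ev) == 0)
    stop_config("c_index: no comparable pairs (no events)")
  fit <- survival::concordance(survival::Surv(times, ev) ~ scores,
                               reverse = TRUE)
  unname(fit$concordance)
}

#' Risk-group survival comparison
#'
#' Splits patients at the probability threshold (default 0.5) into low/high
#' predicted-risk groups and compares their OFR-free survival with
#' Kaplan-Meier curves and a log-rank test.
#'
#' @param probabilities Predicted OFR probabilities.
#' @param records Clinical table with `time_months`, `ofr_event`.
#' @param threshold Probability split point, must lie in (0, 1).
#' @return List with `curves` (low/high `survival_curve`s), `logrank`
#'   (`chi2`, `p`) or `flag = "single_group"`.
#' @export
risk_group_km <- function(probabilities, records, threshold = 0.5) {
  if (!is_probability(threshold) || threshold <= 0 || threshold >= 1)
    stop_config("risk_group_km: threshold must lie strictly in (0, 1)")
  high <- probabilities > threshold
  times <- records$time_months
  events <- records$ofr_event
  if (length(unique(high)) < 2)
    return(list(curves = NULL, logrank = NULL, flag = "single_group"))
  list(curves = list(low = km_estimate(times[!high], events[!high]),
                     high = km_estimate(times[high], events[high])),
       logrank = logrank_test(times, events, high),
       group = ifelse(high, "high", "low"),
       flag = NA_character_)
}
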