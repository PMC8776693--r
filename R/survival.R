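#' Kaplan-Meier estimate of OFR-free survival
#'
#' Product-limit estimator (computed via [survival::survfit]) returned as a
#' plain step-function table. Censored observations leave the risk set after
#' their time.
#'
#' @param times Positive event/censoring times (months).
#' @param events Logical event indicators.
#' @return `data.frame` of class `survival_curve` with columns `time`,
#'   `n_risk`, `n_event`, `surv`.
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0) stop_config("km_estimate: empty input")
  if (any(times <= 0)) stop_config("km_estimate: times must be positive")
  fit <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1,
                           conf.type = "none")
  structure(data.frame(time = fit$time, n_risk = fit$n.risk,
                       n_event = fit$n.event, surv = fit$surv),
            class = c("survival_curve", "data.frame"))
}

#' @rdname km_estimate
#' @param curve A `survival_curve`.
#' @param t Time at which to read the curve (S(t) = 1 before the first
#'   event).
#' @export
km_at <- function(curve, t) {
  s <- c(1, curve$surv)
  idx <- findInterval(t, curve$time) + 1
  s[idx]
}

#' Two-group log-rank test
#'
#' Standard two-group log-rank statistic (observed minus expected over the
#' pooled event times with hypergeometric variance), referred to a 1-df
#' chi-square distribution, via [survival::survdiff]. With no events at all
#' the test is undefined and p = 1 is returned with a flag.
#'
#' @param times,events Survival data.
#' @param group Two-level grouping vector.
#' @return List with `chi2`, `p`, and `flag` (`"no_events"` or `NA`).
#' @export
logrank_test <- function(times, events, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2)
    stop_config("logrank_test: both groups must be non-empty")
  if (sum(events) == 0)
    return(list(chi2 = 0, p = 1, flag = "no_events"))
  sd <- survival::survdiff(survival::Surv(times, as.integer(events)) ~ group)
  chi2 <- sd$chisq
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE),
       flag = NA_character_)
}

#' Cox proportional-hazards fit
#'
#' Multivariate Cox partial-likelihood fit (Newton iterations, Breslow tie
#' handling by default) with guards for constant and collinear covariates.
#' Monotone-likelihood (complete-separation) coefficients are capped at
#' |beta| = 15 and flagged.
#'
#' @param covariates Numeric data.frame/matrix of covariates.
#' @param times,events Survival data.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return List of class `cox_fit` with per-covariate `coef`, `hr`, `se`,
#'   `p`, plus `converged`, `iterations`, `flag`.
#' @export
cox_fit <- function(covariates, times, events, ties = "breslow") {
  X <- as.matrix(as.data.frame(covariates))
  storage.mode(X) <- "double"
  if (any(apply(X, 2, function(c) max(c) - min(c)) == 0))
    stop_config("cox_fit: constant covariate")
  if (qr(cbind(X))$rank < ncol(X))
    stop_config("cox_fit: collinear covariates")
  if (sum(events) < ncol(X))
    stop_config("cox_fit: fewer events than covariates")
  df <- data.frame(X)
  df$.time <- times
  df$.event <- as.integer(events)
  flag <- NA_character_
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(.time, .event) ~ ., data = df, ties = ties,
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 100)),
    warning = function(w) {
      if (grepl("infinite|converge", conditionMessage(w)))
        flag <<- "monotone_likelihood"
      invokeRestart("muffleWarning")
    })
  cf <- coef(fit)
  capped <- abs(cf) > 15
  if (any(capped)) {
    cf[capped] <- sign(cf[capped]) * 15
    flag <- "monotone_likelihood"
  }
  s <- summary(fit)
  structure(list(coef = cf, hr = exp(cf),
                 se = s$coefficients[, "se(coef)"],
                 p = s$coefficients[, "Pr(>|z|)"],
                 converged = is.na(flag), iterations = fit$iter,
                 flag = flag, fit = fit),
            class = "cox_fit")
}

# Table-style dichotomizations of the clinical record used by the screen;
# thresholds are the cohort medians of the study population.
clinical_dichotomies <- function(records, age_cut = 56, diameter_cut = 5.1,
                                 volume_cut = 33, wp_dose_cut = 50,
                                 bt_dose_cut = 24.2) {
  list(
    age_gt = list(label = sprintf("Age >%g", age_cut),
                  x = records$age > age_cut),
    ps2 = list(label = "Performance status 2",
               x = records$performance_status == 2),
    histology_other = list(label = "Non-squamous histology",
                           x = records$histology_class != "scc"),
    diameter_gt = list(label = sprintf("Max diameter >%g cm", diameter_cut),
                       x = records$tumor_max_diameter > diameter_cut),
    volume_gt = list(label = sprintf("Volume >%g ml", volume_cut),
                     x = records$tumor_volume > volume_cut),
    pelvic_ln = list(label = "Pelvic LN metastasis",
                     x = records$pelvic_ln_class != "0"),
    pelvic_ln_ge3 = list(label = "Pelvic LN >=3",
                         x = records$pelvic_ln_class == ">=3"),
    common_iliac = list(label = "Common iliac LN metastasis",
                        x = as.logical(records$common_iliac_ln)),
    paln = list(label = "Para-aortic LN metastasis",
                x = as.logical(records$paln)),
    wp_dose_gt = list(label = sprintf("Whole-pelvis dose >%g Gy", wp_dose_cut),
                      x = records$wp_dose > wp_dose_cut),
    boost = list(label = "LN boost",
                 x = as.logical(records$boost_to_ln)),
    bt_dose_gt = list(label = sprintf("Point-A dose >%g Gy", bt_dose_cut),
                      x = records$bt_pointA_dose > bt_dose_cut),
    chemo_other = list(label = "Non-weekly-cisplatin chemo",
                       x = records$chemo_class != "weekly_cddp"))
}

#' Prognostic screening of clinical variables
#'
#' Reproduces the classic prognostic-factor table: every clinical variable
#' is dichotomized at its conventional threshold (age 56 y, diameter 5.1 cm,
#' volume 33 ml, whole-pelvis dose 50 Gy, point-A dose 24.2 Gy, nodal
#' statuses as recorded), per-variable 3-year OFR-free percentages are read
#' off the Kaplan-Meier curve at month 36, each variable gets a univariate
#' log-rank test, and a single multivariate Cox model over all non-degenerate
#' variables provides adjusted p-values. The variables significant (p < alpha)
#' in both tests are marked `selected` — the clinical predictors the
#' prediction model should use.
#'
#' @param records Clinical table (see [sample_clinical_table()]).
#' @param alpha Significance level (default 0.05).
#' @param ... Threshold overrides passed to the dichotomizer (`age_cut`,
#'   `diameter_cut`, `volume_cut`, `wp_dose_cut`, `bt_dose_cut`).
#' @return `data.frame` with columns `variable`, `label`, `n_high`,
#'   `ofr_free_3y_high_pct`, `ofr_free_3y_low_pct`, `logrank_p`, `cox_p`,
#'   `selected`, `note`.
#' @export
prognostic_screen <- function(records, alpha = 0.05, ...) {
  dich <- clinical_dichotomies(records, ...)
  times <- records$time_months
  events <- records$ofr_event
  rows <- list()
  usable <- list()
  for (nm in names(dich)) {
    x <- dich[[nm]]$x
    note <- NA_character_
    if (length(unique(x)) < 2) {
      rows[[nm]] <- data.frame(variable = nm, label = dich[[nm]]$label,
                               n_high = sum(x),
                               ofr_free_3y_high_pct = NA, ofr_free_3y_low_pct = NA,
                               logrank_p = NA, cox_p = NA, selected = FALSE,
                               note = "degenerate stratum, skipped")
      next
    }
    hi <- km_at(km_estimate(times[x], events[x]), 36)
    lo <- km_at(km_estimate(times[!x], events[!x]), 36)
    lr <- logrank_test(times, events, x)
    usable[[nm]] <- as.numeric(x)
    rows[[nm]] <- data.frame(variable = nm, label = dich[[nm]]$label,
                             n_high = sum(x),
                             ofr_free_3y_high_pct = 100 * hi,
                             ofr_free_3y_low_pct = 100 * lo,
                             logrank_p = lr$p, cox_p = NA_real_,
                             selected = FALSE, note = note)
  }
  out <- do.call(rbind, rows)
  if (length(usable) >= 1 && sum(events) > length(usable)) {
    X <- as.data.frame(usable)
    keep <- qr(as.matrix(X))$rank == ncol(X)
    if (!keep) {  # drop aliased columns, keep the first of each group
      q <- qr(as.matrix(X))
      X <- X[, q$pivot[seq_len(q$rank)], drop = FALSE]
    }
    cx <- cox_fit(X, times, events)
    out$cox_p[match(colnames(X), out$variable)] <- unname(cx$p)
  }
  out$selected <- !is.na(out$logrank_p) & !is.na(out$cox_p) &
    out$logrank_p < alpha & out$cox_p < alpha
  rownames(out) <- NULL
  out
}
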