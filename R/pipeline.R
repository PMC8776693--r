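#' Run the full simulate-extract-select-train-evaluate-report pipeline
#'
#' Orchestrates the whole analysis as a configured, logged, reproducible
#' run: simulate the phantom cohort, extract the radiomics feature table,
#' run the survival-based selector on the full cohort (reported for
#' inspection; fold-wise selection is still re-run inside the
#' cross-validation), evaluate the configured designs, and write a report.
#' All randomness flows from the single config seed.
#'
#' @param config Path to a YAML config file, or an equivalent named list.
#'   Recognized fields (all optional): `seed`, `normalization`
#'   (`"zscore"`/`"minmax"`), `n_levels`, `scheme` (`"fivefold"`, ...),
#'   `n_folds`, `designs`, `n_boot`, `write_images` (default FALSE), plus a
#'   `cohort:` block passed to [cohort_config()].
#' @param out_dir Output directory for the run artifacts.
#' @return The `ofr_experiment`, invisibly; artifacts are written to
#'   `out_dir` (`features.csv`, `selection.json`, `summary.json`,
#'   `report.pdf`, `log.txt`, and `cohort/` when `write_images`).
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "log.txt")
  cat("", file = logf)
  stamp <- function(stage, t0) {
    cat(sprintf("%s: %.2f s\n", stage,
                as.numeric(proc.time()[3] - t0)), file = logf, append = TRUE)
  }
  seed <- config$seed %||% 1L
  cohort_args <- config$cohort %||% list()
  cohort_args$seed <- cohort_args$seed %||% seed
  cfg <- do.call(cohort_config, cohort_args)

  t0 <- proc.time()[3]
  cohort <- simulate_cohort(cfg)
  if (isTRUE(config$write_images))
    write_cohort(cohort, file.path(out_dir, "cohort"))
  stamp("simulate", t0)

  t0 <- proc.time()[3]
  features <- extract_cohort_features(
    cohort, normalization = config$normalization %||% "zscore",
    n_levels = config$n_levels %||% 32L)
  write.csv(features, file.path(out_dir, "features.csv"), row.names = FALSE)
  stamp("extract", t0)

  t0 <- proc.time()[3]
  ranked <- km_rank_features(features, cohort$records)
  sel <- prune_and_take(ranked, features)
  jsonlite::write_json(
    list(kept = sel$kept,
         dropped_for_correlation = sel$dropped_for_correlation,
         top_ranked = head(ranked, 20)),
    file.path(out_dir, "selection.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  stamp("select", t0)

  t0 <- proc.time()[3]
  exper <- run_experiment(
    features, cohort$records,
    designs = config$designs %||% c("clinical_only", "radiomics_only",
                                    "combined"),
    scheme_kind = config$scheme %||% "fivefold",
    n_folds = config$n_folds %||% 5L,
    seed = seed, n_boot = config$n_boot %||% 2000)
  stamp("evaluate", t0)

  t0 <- proc.time()[3]
  write_report(exper, cohort$records, out_dir)
  stamp("report", t0)
  invisible(exper)
}

# summary JSON shaped like the study's results paragraphs, plus basic
# ROC / KM figures
write_report <- function(exper, records, out_dir) {
  summ <- list(manifest = exper$manifest)
  for (d in names(exper$designs)) {
    r <- exper$designs[[d]]
    summ[[d]] <- list(family = r$family,
                      auc_mean = r$mean_auc, auc_sd = r$sd_auc,
                      auc_pooled = r$pooled_auc,
                      fold_auc = unname(r$fold_auc),
                      accuracy = unname(r$metrics$mean["accuracy"]),
                      sensitivity = unname(r$metrics$mean["sensitivity"]),
                      specificity = unname(r$metrics$mean["specificity"]))
  }
  if (!is.null(exper$comparison)) {
    cmp <- exper$comparison
    summ$combined_vs_clinical <- list(
      nri = cmp$nri$estimate, nri_ci = cmp$nri$ci, nri_p = cmp$nri$p,
      idi = cmp$idi$estimate, idi_ci = cmp$idi$ci, idi_p = cmp$idi$p,
      c_index_clinical = cmp$c_index_clinical,
      c_index_combined = cmp$c_index_combined,
      risk_group_logrank_p = exper$risk_groups$combined$logrank$p)
  }
  jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  grDevices::pdf(file.path(out_dir, "report.pdf"), width = 9, height = 4.5)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, 2))
  graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1), xlab = "1 - specificity",
                 ylab = "sensitivity", main = "Pooled out-of-fold ROC")
  graphics::abline(0, 1, lty = 3, col = "gray")
  cols <- setNames(c("black", "steelblue", "firebrick"),
                   c("clinical_only", "radiomics_only", "combined"))
  for (d in names(exper$designs)) {
    cv <- exper$designs[[d]]$roc$curve
    graphics::lines(cv$fpr, cv$tpr, col = cols[[d]] %||% "gray40", lwd = 2)
  }
  graphics::legend("bottomright", legend = names(exper$designs),
                   col = cols[names(exper$designs)], lwd = 2, bty = "n")
  rg <- exper$risk_groups$combined
  if (!is.null(rg) && !is.null(rg$curves)) {
    graphics::plot(NA, xlim = c(0, 96), ylim = c(0, 1), xlab = "months",
                   ylab = "OFR-free survival",
                   main = "Predicted risk groups (combined)")
    step_line <- function(curve, col) {
      graphics::lines(stats::stepfun(curve$time, c(1, curve$surv)),
                      xval = seq(0, 96, by = 0.5), col = col, lwd = 2,
                      do.points = FALSE)
    }
    step_line(rg$curves$low, "steelblue")
    step_line(rg$curves$high, "firebrick")
    graphics::legend("bottomleft",
                     legend = c("low risk", "high risk",
                                sprintf("log-rank p = %.3g", rg$logrank$p)),
                     col = c("steelblue", "firebrick", NA), lwd = c(2, 2, NA),
                     bty = "n")
  }
  invisible(file.path(out_dir, "summary.json"))
}
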