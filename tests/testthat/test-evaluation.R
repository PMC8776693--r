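test_that("stratified five-fold partitions are balanced and reproducible", {
  rec <- sample_clinical_table(cohort_config(seed = 2))
  sch <- assign_folds(rec, "fivefold", seed = 9)
  sizes <- vapply(sch$splits, function(s) length(s$test), 0L)
  expect_equal(sum(sizes), 180)
  expect_true(all(sizes %in% 35:37))  # 180 patients over 5 folds
  expect_equal(sort(unlist(lapply(sch$splits, `[[`, "test"))), 1:180)
  sch2 <- assign_folds(rec, "fivefold", seed = 9)
  expect_identical(lapply(sch$splits, `[[`, "test"),
                   lapply(sch2$splits, `[[`, "test"))
})

test_that("institution schemes never test on event-free institutions", {
  rec <- sample_clinical_table(cohort_config(seed = 2))
  loio <- assign_folds(rec, "leave_one_institution_out", seed = 1)
  tested_inst <- vapply(loio$splits, `[[`, "", "name")
  expect_false(any(c("H", "J") %in% tested_inst))
  # H and J patients always sit in training
  for (s in loio$splits)
    expect_true(all(which(rec$institution %in% c("H", "J")) %in% s$train))
  hold <- assign_folds(rec, "three_institution_holdout", seed = 1)
  expect_setequal(vapply(hold$splits, `[[`, "", "name"), c("E", "L", "M"))
  expect_true(all(vapply(hold$splits, function(s)
    length(s$inner_folds) == length(s$train), TRUE)))
})

test_that("AUC follows the rank formulation with ties", {
  expect_equal(roc_and_auc(c(.9, .8, .2, .1), c(1, 1, 0, 0))$auc, 1)
  # the published PALN contingency as a binary marker:
  # sensitivity 12/38, specificity 133/142 -> AUC = (sens + spec) / 2
  paln <- c(rep(1, 12), rep(0, 26), rep(1, 9), rep(0, 133))
  y <- c(rep(1, 38), rep(0, 142))
  expect_equal(roc_and_auc(paln, y)$auc, (12 / 38 + 133 / 142) / 2,
               tolerance = 1e-12)
  # independent scores hover at 1/2
  withr::with_seed(31, {
    s <- runif(1e4)
    yy <- rbinom(1e4, 1, 0.3)
  })
  expect_lt(abs(roc_and_auc(s, yy)$auc - 0.5), 0.02)
  expect_error(roc_and_auc(s, rep(1, 1e4)), "both classes")
})

test_that("AUC and curve agree with the pROC reference", {
  skip_if_not_installed("pROC")
  withr::with_seed(17, {
    s <- round(runif(300), 2)  # coarse scores force ties
    y <- rbinom(300, 1, plogis(3 * (s - 0.5)))
  })
  ours <- roc_and_auc(s, y)
  ref <- pROC::roc(y, s, direction = "<", levels = c(0, 1), quiet = TRUE)
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
})

test_that("threshold metrics reduce to the hand confusion matrix", {
  m <- threshold_metrics(c(.9, .6, .4, .1), c(1, 1, 0, 0))
  expect_equal(unname(m), c(1, 1, 1))
  expect_equal(threshold_metrics(c(.9, .6, .4, .1), c(1, 1, 0, 0),
                                 threshold = 0)[["sensitivity"]], 1)
  deg <- threshold_metrics(rep(1, 4), rep(1, 4))
  expect_equal(deg[["accuracy"]], 1)
  expect_true(is.na(deg[["specificity"]]))
})

test_that("NRI and IDI match hand computation and are antisymmetric", {
  p_ref <- c(0.2, 0.4, 0.5)
  p_new <- c(0.3, 0.5, 0.4)
  y <- c(1, 1, 0)
  r_nri <- nri(p_ref, p_new, y, n_boot = 200, seed = 1)
  r_idi <- idi(p_ref, p_new, y, n_boot = 200, seed = 1)
  expect_equal(r_nri$estimate, 2)
  expect_equal(r_idi$estimate, 0.2, tolerance = 1e-12)
  # identical vectors -> exact zeros
  expect_equal(nri(p_ref, p_ref, y, n_boot = 50)$estimate, 0)
  expect_equal(idi(p_ref, p_ref, y, n_boot = 50)$estimate, 0)
  # swapping reference and new negates both
  expect_equal(nri(p_new, p_ref, y, n_boot = 50)$estimate, -2)
  expect_equal(idi(p_new, p_ref, y, n_boot = 50)$estimate, -0.2,
               tolerance = 1e-12)
  expect_error(nri(p_ref, p_new[1:2], y), "same patients")
})

test_that("concordance matches hand pair counting", {
  # perfect concordance: risk equals negated event time, all events
  t <- c(2, 5, 7, 9, 11)
  expect_equal(c_index(-t, t, rep(TRUE, 5)), 1)
  # constant scores tie every pair
  expect_equal(c_index(rep(1, 5), t, rep(TRUE, 5)), 0.5)
  # 5 subjects, one censored: times 1e, 3e, 4c, 6e, 8e; a pair is comparable
  # when the earlier time is an event, so the censored subject only pairs
  # with the events at 1 and 3
  times <- c(1, 3, 4, 6, 8)
  events <- c(TRUE, TRUE, FALSE, TRUE, TRUE)
  scores <- c(10, 8, 9, 2, 4)
  # comparable pairs: (1,2),(1,3),(1,4),(1,5),(2,3),(2,4),(2,5),(4,5)
  # concordant: (1,2) 10>8 T; (1,3) 10>9 T; (1,4) 10>2 T; (1,5) 10>4 T;
  # (2,3) 8<9 F; (2,4) 8>2 T; (2,5) 8>4 T; (4,5) 2<4 F  -> 6/8
  expect_equal(c_index(scores, times, events), 6 / 8)
  expect_error(c_index(scores, times, rep(FALSE, 5)), "no comparable")
})

test_that("risk-group survival splits behave at the threshold", {
  rec <- toy_cohort_records(100, seed = 44)
  # probabilities equal to the label maximally separate the curves
  p <- as.numeric(rec$ofr_event)
  rg <- risk_group_km(p, rec)
  expect_lt(rg$logrank$p, 0.01)
  expect_equal(sort(names(rg$curves)), c("high", "low"))
  # a single group is flagged, not tested
  rg1 <- risk_group_km(rep(0.9, 100), rec)
  expect_equal(rg1$flag, "single_group")
  expect_error(risk_group_km(p, rec, threshold = 1.5), "threshold")
})
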