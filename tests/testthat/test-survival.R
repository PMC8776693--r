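test_that("the product-limit estimator matches hand computation", {
  # three subjects, all events
  km <- km_estimate(c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  # all censored -> S stays at 1
  kmc <- km_estimate(c(5, 7, 9), c(FALSE, FALSE, FALSE))
  expect_true(all(kmc$surv == 1))
  # five subjects with two censored: hand product over risk sets
  # times 1(e) 2(c) 3(e) 4(c) 5(e): S = 4/5, 4/5 * 2/3, then * 0
  km5 <- km_estimate(c(1, 2, 3, 4, 5), c(TRUE, FALSE, TRUE, FALSE, TRUE))
  ev <- km5[km5$n_event > 0, ]
  expect_equal(ev$surv, c(4 / 5, 4 / 5 * 2 / 3, 0))
  # without censoring KM equals the empirical survivor function
  withr::with_seed(1, t <- sample(1:20, 50, replace = TRUE))
  kme <- km_estimate(t, rep(TRUE, 50))
  expect_equal(kme$surv, vapply(kme$time, function(u) mean(t > u), 0))
  expect_equal(km_at(kme, 0.5), 1)
  expect_error(km_estimate(numeric(0), logical(0)), "empty")
})

test_that("the log-rank test detects separation and respects symmetry", {
  # identical groups -> chi2 = 0, p = 1
  t <- c(1, 3, 5, 7, 9, 1, 3, 5, 7, 9)
  e <- rep(TRUE, 10)
  g <- rep(c("a", "b"), each = 5)
  lr <- logrank_test(t, e, g)
  expect_equal(lr$chi2, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)
  # complete separation at n = 20 per arm
  t2 <- c(1:20, 101:120)
  lr2 <- logrank_test(t2, rep(TRUE, 40), rep(c("a", "b"), each = 20))
  expect_lt(lr2$p, 0.001)
  # invariant to swapping group labels
  lr2b <- logrank_test(t2, rep(TRUE, 40), rep(c("b", "a"), each = 20))
  expect_equal(lr2$chi2, lr2b$chi2)
  # no events anywhere -> flagged p = 1
  lr3 <- logrank_test(t, rep(FALSE, 10), g)
  expect_equal(lr3$p, 1)
  expect_equal(lr3$flag, "no_events")
})

test_that("log-rank type-I error is nominal under the null", {
  alpha_hits <- withr::with_seed(99, {
    vapply(1:2000, function(r) {
      t <- rexp(100, 0.05)
      e <- t <= 36
      time <- ifelse(e, t, 36)
      g <- rep(c(0, 1), each = 50)
      logrank_test(time, e, g)$p < 0.05
    }, logical(1))
  })
  expect_gte(mean(alpha_hits), 0.03)
  expect_lte(mean(alpha_hits), 0.07)
})

test_that("Cox regression recovers a known hazard ratio", {
  withr::with_seed(123, {
    n <- 2000
    x <- rbinom(n, 1, 0.5)
    t <- rexp(n, rate = 0.03 * 3^x)
    cens <- runif(n, 10, 60)
    time <- pmin(t, cens)
    event <- t <= cens
  })
  fit <- cox_fit(data.frame(x = x), time, event)
  expect_gt(unname(fit$hr["x"]), 2.5)
  expect_lt(unname(fit$hr["x"]), 3.6)
  expect_true(fit$converged)
  expect_equal(unname(fit$hr), unname(exp(fit$coef)))

  # a null covariate stays near zero
  withr::with_seed(5, z <- rnorm(2000))
  fit0 <- cox_fit(data.frame(z = z), time, event)
  expect_lt(abs(fit0$coef["z"]), 0.1)

  # collinearity and constants are refused
  expect_error(cox_fit(data.frame(a = x, b = x), time, event), "collinear")
  expect_error(cox_fit(data.frame(a = rep(1, n)), time, event), "constant")
})

test_that("the prognostic screen flags only the planted predictor", {
  withr::with_seed(43, {
    n <- 300
    paln <- rbinom(n, 1, 0.15) == 1
    t <- rexp(n, rate = 0.004 * ifelse(paln, 8, 1))
    event <- t <= 36
    rec <- data.frame(
      patient_id = sprintf("P%03d", 1:n),
      age = sample(30:80, n, TRUE),
      performance_status = sample(0:2, n, TRUE, prob = c(.7, .25, .05)),
      histology_class = sample(c("scc", "other"), n, TRUE, c(.9, .1)),
      tumor_max_diameter = runif(n, 2, 12),
      tumor_volume = runif(n, 3, 200),
      pelvic_ln_class = sample(c("0", "1-2", ">=3"), n, TRUE),
      common_iliac_ln = rbinom(n, 1, 0.1) == 1,
      paln = paln,
      wp_dose = runif(n, 45, 60),
      boost_to_ln = rbinom(n, 1, 0.3) == 1,
      bt_pointA_dose = runif(n, 12, 36),
      chemo_class = sample(c("weekly_cddp", "other"), n, TRUE, c(.75, .25)),
      ofr_event = event,
      time_months = ifelse(event, pmax(t, 0.5), runif(n, 36, 96)))
  })
  scr <- prognostic_screen(rec)
  expect_true(scr$selected[scr$variable == "paln"])
  expect_equal(sum(scr$selected), 1)
  # thresholds echo the configuration
  expect_true(any(grepl("5.1", scr$label)))
  expect_true(any(grepl("33", scr$label)))
  # a cohort with no events yields p = 1 everywhere and no selection
  rec0 <- rec
  rec0$ofr_event <- FALSE
  rec0$time_months <- runif(nrow(rec0), 36, 96)
  scr0 <- prognostic_screen(rec0)
  expect_true(all(scr0$logrank_p == 1, na.rm = TRUE))
  expect_false(any(scr0$selected))
})
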