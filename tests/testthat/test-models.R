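test_that("class weights balance the loss across classes", {
  y <- c(rep(1, 38), rep(0, 142))  # the study's event split
  w <- class_weights(y)
  expect_equal(unname(w["w_pos"]), 180 / 76, tolerance = 1e-12)
  expect_equal(unname(w["w_neg"]), 180 / 284, tolerance = 1e-12)
  expect_equal(unname(w["w_pos"] * 38 + w["w_neg"] * 142), 180)
  expect_equal(unname(class_weights(c(0, 0, 1, 1))), c(1, 1))
  expect_error(class_weights(rep(1, 5)), "both classes")
})

test_that("penalized fits behave at the shrinkage extremes", {
  withr::with_seed(2, {
    X <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
    y <- rbinom(100, 1, 0.3)
  })
  # lambda -> infinity: intercept-only model predicting the weighted rate
  fit <- fit_penalized(X, y, "lasso", lambda_grid = c(1e6), loo = FALSE)
  expect_equal(unname(fit$coefficients), c(0, 0))
  p <- predict_probability(fit, X)
  expect_equal(unique(round(p, 10)), round(0.5, 10))  # balanced weights

  # a separable single feature at small lambda gives training AUC 1
  Xs <- matrix(c(rnorm(50, -3), rnorm(50, 3)), ncol = 1,
               dimnames = list(NULL, "s"))
  ys <- rep(c(0, 1), each = 50)
  fsep <- fit_penalized(Xs, ys, "lasso", lambda_grid = c(1e-4), loo = FALSE)
  expect_equal(roc_and_auc(predict_probability(fsep, Xs), ys)$auc, 1)
  expect_error(fit_penalized(X * NA, y, "lasso"), "non-finite")
})

test_that("the lasso recovers planted logistic coefficients", {
  withr::with_seed(6, {
    n <- 500
    X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
    beta <- c(1.2, -0.9, 0.7, 0, 0, 0)
    y <- rbinom(n, 1, plogis(X %*% beta))
  })
  fit <- fit_penalized(X, y, "lasso")
  cf <- fit$coefficients
  expect_true(all(sign(cf[1:3]) == sign(beta[1:3])))
  expect_lt(sqrt(mean((cf[1:3] - beta[1:3])^2)), 0.25)
})

test_that("LOO tuning tracks held-out performance and ties go upward", {
  # with pure-noise features, heavy shrinkage should win the LOO criterion
  withr::with_seed(14, {
    X <- matrix(rnorm(60 * 5), 60, 5, dimnames = list(NULL, paste0("n", 1:5)))
    y <- rbinom(60, 1, 0.4)
  })
  fit <- fit_penalized(X, y, "lasso", lambda_grid = 10^seq(-3, 2, length = 20))
  expect_gt(fit$lambda, 1e-3)
  expect_length(fit$loo_loglik, 20)
  # strong signal: LOO must not collapse to the most penalized model
  withr::with_seed(15, {
    Xs <- matrix(rnorm(60 * 2), 60, 2, dimnames = list(NULL, c("s", "z")))
    ys <- rbinom(60, 1, plogis(3 * Xs[, 1]))
  })
  fs <- fit_penalized(Xs, ys, "lasso")
  expect_lt(fs$lambda, 1)
  expect_gt(abs(fs$coefficients["s"]), 0.2)
})

test_that("weighted and unweighted fits coincide on balanced data", {
  withr::with_seed(3, {
    X <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
    y <- rep(c(0, 1), 50)
  })
  f1 <- fit_penalized(X, y, "ridge", class_weighting = TRUE,
                      lambda_grid = c(0.1), loo = FALSE)
  f2 <- fit_penalized(X, y, "ridge", class_weighting = FALSE,
                      lambda_grid = c(0.1), loo = FALSE)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-7)
})

test_that("naive Bayes separates Gaussian clusters and matches e1071", {
  skip_if_not_installed("e1071")
  withr::with_seed(5, {
    n <- 200
    X <- rbind(matrix(rnorm(n, -2), n / 2, 2),
               matrix(rnorm(n, 2), n / 2, 2))
    colnames(X) <- c("u", "v")
    y <- rep(c(0, 1), each = n / 2)
    Xtest <- rbind(matrix(rnorm(n, -2), n / 2, 2),
                   matrix(rnorm(n, 2), n / 2, 2))
    colnames(Xtest) <- c("u", "v")
  })
  fit <- fit_naive_bayes(X, y)
  p <- predict_probability(fit, Xtest)
  expect_gt(mean((p > 0.5) == y), 0.95)
  # against the reference implementation (unweighted priors, balanced data)
  ref <- e1071::naiveBayes(data.frame(X), factor(y))
  pref <- predict(ref, data.frame(Xtest), type = "raw")[, "1"]
  expect_equal(p, unname(pref), tolerance = 1e-6)
  # zero-variance feature is floored, not fatal
  Xz <- cbind(X, flat = 1)
  expect_equal(fit_naive_bayes(Xz, y)$flag, "variance_floored")
})

test_that("random forest is seeded and honors a perfect split", {
  withr::with_seed(21, {
    X <- data.frame(perfect = rep(c(0, 1), each = 30),
                    noise = rnorm(60))
    y <- rep(c(0, 1), each = 30)
  })
  f1 <- fit_random_forest(X, y, n_trees = 50, seed = 7)
  f2 <- fit_random_forest(X, y, n_trees = 50, seed = 7)
  expect_identical(predict_probability(f1, X), predict_probability(f2, X))
  one <- fit_random_forest(X[, "perfect", drop = FALSE], y, n_trees = 1,
                           mtry = 1, seed = 3)
  p <- predict_probability(one, X[, "perfect", drop = FALSE])
  expect_equal(p, y)  # a single stump reproduces the perfect feature
})

test_that("design matrices follow the three-design contract", {
  pc <- planted_feature_cohort(40, seed = 2)
  d1 <- make_design(pc$records, design = "clinical_only")
  expect_equal(colnames(d1$X), "paln")
  expect_equal(d1$y, as.integer(pc$records$ofr_event &
                                  pc$records$time_months <= 36))
  d2 <- make_design(pc$records, pc$features, "combined",
                    feature_names = paste0("inf", 1:3))
  expect_equal(ncol(d2$X), 4)
  expect_error(make_design(pc$records, pc$features, "combined",
                           feature_names = "nope"), "unknown feature")
  short <- pc$features[-3, ]
  expect_error(make_design(pc$records, short, "radiomics_only"), "P003")
})

test_that("predicted probabilities are proper and monotone", {
  withr::with_seed(30, {
    X <- matrix(rnorm(100), 50, 2, dimnames = list(NULL, c("a", "b")))
    y <- rbinom(50, 1, plogis(2 * X[, 1]))
  })
  fit <- fit_penalized(X, y, "ridge", lambda_grid = c(0.01), loo = FALSE)
  p <- predict_probability(fit, X)
  expect_true(all(p >= 0 & p <= 1))
  grid <- cbind(a = seq(-3, 3, length = 20), b = 0)
  expect_true(all(diff(predict_probability(fit, grid)) *
                    sign(fit$coefficients["a"]) > 0))
  expect_error(predict_probability(fit, X[, 1, drop = FALSE]), "missing")
})
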