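#' Balanced class weights for imbalanced outcomes
#'
#' Loss weights correcting for class imbalance: `w_c = n / (2 n_c)`, so each
#' class contributes half of the total weighted loss and
#' `w_pos n_pos + w_neg n_neg = n`.
#'
#' @param labels Binary labels (logical or 0/1).
#' @return Named vector `c(w_pos, w_neg)`.
#' @export
class_weights <- function(labels) {
  y <- as.integer(as.logical(labels))
  n_pos <- sum(y == 1)
  n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0)
    stop_config("class_weights: both classes must be present")
  n <- length(y)
  c(w_pos = n / (2 * n_pos), w_neg = n / (2 * n_neg))
}

default_lambda_grid <- function() 10^seq(-4, 2, length.out = 50)

# per-observation weights from the class-weight correction (or 1s when off)
observation_weights <- function(y, class_weighting) {
  if (!class_weighting) return(rep(1, length(y)))
  w <- class_weights(y)
  ifelse(y == 1, w["w_pos"], w["w_neg"])
}

#' Fit a penalized logistic model with LOO-tuned regularization
#'
#' Penalized (LASSO or Ridge) logistic regression with class-weighted
#' log-loss. Features are standardized with training means/SDs stored in the
#' model (constant columns are left centered only). The penalty strength is
#' chosen from a log-spaced grid by leave-one-out weighted log-likelihood
#' within the training data; ties go to the larger (more regularized)
#' lambda. Fitting is delegated to [glmnet::glmnet] on the standardized
#' design.
#'
#' @param X Numeric matrix/data.frame of features (columns named).
#' @param y Binary outcome (logical or 0/1).
#' @param family `"lasso"` (alpha = 1) or `"ridge"` (alpha = 0).
#' @param class_weighting Apply the balanced class weights (default TRUE).
#' @param lambda_grid Penalty grid (default 50 values, 1e-4 to 1e2).
#' @param loo Tune lambda by leave-one-out (default TRUE); FALSE picks the
#'   smallest grid value (effectively unpenalized).
#' @return Object of class `penalized_fit` with `coefficients` (named, on
#'   the original feature scale of the standardized design), `intercept`,
#'   `lambda`, `loo_loglik` per grid value, standardization parameters and
#'   the training feature names.
#' @export
fit_penalized <- function(X, y, family = c("lasso", "ridge"),
                          class_weighting = TRUE,
                          lambda_grid = default_lambda_grid(),
                          loo = TRUE) {
  family <- match.arg(family)
  X <- as.matrix(as.data.frame(X))
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) stop_config("fit_penalized: non-finite features")
  y <- as.integer(as.logical(y))
  if (length(unique(y)) < 2 || min(table(y)) < 2)
    stop_config("fit_penalized: need >= 2 samples per class")
  w <- observation_weights(y, class_weighting)
  centers <- colMeans(X)
  scales <- apply(X, 2, sd)
  scales[scales == 0] <- 1
  Xs <- scale(X, center = centers, scale = scales)
  alpha <- if (family == "lasso") 1 else 0
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  # glmnet needs >= 2 columns; a zero column is inert under both penalties
  pad <- ncol(Xs) < 2
  design <- if (pad) cbind(Xs, .pad = 0) else Xs
  fit_path <- function(Xd, yd, wd) {
    # small LOO subsets trigger glmnet's sample-size caution; class balance
    # is already guarded above
    withCallingHandlers(
      glmnet::glmnet(Xd, yd, family = "binomial", weights = wd,
                     alpha = alpha, lambda = lambda_grid,
                     standardize = FALSE),
      warning = function(w) {
        if (grepl("fewer than|dangerous", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
  }
  # a degenerate subset (all predictors constant) falls back to the
  # intercept-only model predicting the weighted base rate
  base_rate <- function(yd, wd) sum(wd * yd) / sum(wd)
  loo_ll <- rep(NA_real_, length(lambda_grid))
  if (loo && length(lambda_grid) > 1) {
    ll <- matrix(0, length(y), length(lambda_grid))
    ok <- TRUE
    for (i in seq_along(y)) {
      yi <- y[-i]
      if (length(unique(yi)) < 2) { ok <- FALSE; break }
      p <- tryCatch({
        f <- fit_path(design[-i, , drop = FALSE], yi, w[-i])
        drop(predict(f, design[i, , drop = FALSE], type = "response",
                     s = lambda_grid, exact = FALSE))
      }, error = function(e) rep(base_rate(yi, w[-i]), length(lambda_grid)))
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      ll[i, ] <- w[i] * (y[i] * log(p) + (1 - y[i]) * log(1 - p))
    }
    if (ok) {
      loo_ll <- colSums(ll)
      best <- max(which(loo_ll >= max(loo_ll) - 1e-10))  # tie -> larger lambda
      lambda <- lambda_grid[best]
    } else lambda <- min(lambda_grid)
  } else {
    lambda <- min(lambda_grid)
  }
  beta <- tryCatch({
    final <- fit_path(design, y, w)
    drop(as.matrix(coef(final, s = lambda)))
  }, error = function(e) {
    c(qlogis(base_rate(y, w)), numeric(ncol(design)))
  })
  coefs <- beta[-1]
  names(coefs) <- colnames(design)
  if (pad) coefs <- coefs[names(coefs) != ".pad"]
  names(coefs) <- colnames(Xs)
  structure(list(family = family, coefficients = coefs,
                 intercept = beta[1], lambda = lambda,
                 lambda_grid = lambda_grid, loo_loglik = loo_ll,
                 centers = centers, scales = scales,
                 feature_names = colnames(Xs),
                 class_weights = if (class_weighting) class_weights(y) else
                   c(w_pos = 1, w_neg = 1)),
            class = "penalized_fit")
}

#' Gaussian naive Bayes with weighted priors
#'
#' Gaussian class-conditional naive Bayes classifier whose class priors are
#' the *weighted* class frequencies (uniform under the balanced class
#' weights). Zero-variance class-conditional features have their variance
#' floored at a small epsilon and are flagged.
#'
#' @inheritParams fit_penalized
#' @param var_floor Variance floor (default 1e-8).
#' @return Object of class `nb_fit`.
#' @export
fit_naive_bayes <- function(X, y, class_weighting = TRUE,
                            var_floor = 1e-8) {
  X <- as.matrix(as.data.frame(X))
  y <- as.integer(as.logical(y))
  if (length(unique(y)) < 2)
    stop_config("fit_naive_bayes: both classes required")
  w <- observation_weights(y, class_weighting)
  priors <- c(`0` = sum(w[y == 0]), `1` = sum(w[y == 1]))
  priors <- priors / sum(priors)
  stats_for <- function(cls) {
    Xi <- X[y == cls, , drop = FALSE]
    v <- apply(Xi, 2, var)  # sample variance, the usual Gaussian-NB choice
    list(mean = colMeans(Xi), var = pmax(v, var_floor),
         floored = v < var_floor)
  }
  by_class <- list(`0` = stats_for(0), `1` = stats_for(1))
  structure(list(priors = priors, by_class = by_class,
                 feature_names = colnames(X),
                 flag = if (any(by_class$`0`$floored | by_class$`1`$floored))
                   "variance_floored" else NA_character_),
            class = "nb_fit")
}

#' Random forest classifier (Gini impurity)
#'
#' Seeded random forest with Gini-impurity splits via
#' [randomForest::randomForest]; class weights from [class_weights()] are
#' passed as `classwt`. Defaults: 500 trees, `sqrt(p)` candidate features
#' per split.
#'
#' @inheritParams fit_penalized
#' @param n_trees Number of trees (default 500).
#' @param mtry Features tried per split (default `floor(sqrt(p))`).
#' @param seed Integer seed making the forest deterministic.
#' @return Object of class `rf_fit`.
#' @export
fit_random_forest <- function(X, y, class_weighting = TRUE, n_trees = 500,
                              mtry = NULL, seed = 1L) {
  X <- as.data.frame(X)
  y <- factor(as.integer(as.logical(y)), levels = c(0, 1))
  if (nlevels(droplevels(y)) < 2)
    stop_config("fit_random_forest: both classes required")
  cw <- if (class_weighting) {
    w <- class_weights(y == "1")
    c(`0` = unname(w["w_neg"]), `1` = unname(w["w_pos"]))
  } else c(`0` = 1, `1` = 1)
  if (is.null(mtry)) mtry <- max(1, floor(sqrt(ncol(X))))
  fit <- withr::with_seed(seed, randomForest::randomForest(
    x = X, y = y, ntree = n_trees, mtry = mtry, classwt = cw))
  structure(list(fit = fit, feature_names = colnames(X), seed = seed),
            class = "rf_fit")
}

#' Build the model design matrix for a cohort
#'
#' Assembles the feature matrix and outcome for one of the three designs:
#' `clinical_only` uses the PALN indicator alone (the single clinical
#' predictor retained by the prognostic screen), `radiomics_only` the given
#' radiomics columns, `combined` their concatenation. The outcome is the
#' OFR-within-36-months indicator.
#'
#' @param records Clinical table.
#' @param features Radiomics feature table (may be `NULL` for
#'   `clinical_only`).
#' @param design `"clinical_only"`, `"radiomics_only"` or `"combined"`.
#' @param feature_names Radiomics columns to use (default: all).
#' @return List with matrix `X` and binary vector `y`.
#' @export
make_design <- function(records, features = NULL,
                        design = c("clinical_only", "radiomics_only",
                                   "combined"),
                        feature_names = NULL) {
  design <- match.arg(design)
  y <- as.integer(as.logical(records$ofr_event) & records$time_months <= 36)
  clin <- matrix(as.numeric(as.logical(records$paln)), ncol = 1,
                 dimnames = list(NULL, "paln"))
  if (design == "clinical_only") return(list(X = clin, y = y))
  R <- feature_matrix(features, records)
  if (!is.null(feature_names)) {
    missing <- setdiff(feature_names, colnames(R))
    if (length(missing))
      stop_config("make_design: unknown feature(s) %s",
                  paste(missing, collapse = ", "))
    R <- R[, feature_names, drop = FALSE]
  }
  X <- switch(design, radiomics_only = R, combined = cbind(clin, R))
  list(X = X, y = y)
}

#' Predict OFR probability
#'
#' Per-patient probability of out-of-field recurrence within 36 months from
#' a fitted model. Columns are matched by the training feature names.
#'
#' @param model A `penalized_fit`, `nb_fit` or `rf_fit`.
#' @param X New feature matrix with the training columns.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_probability <- function(model, X) {
  UseMethod("predict_probability")
}

align_columns <- function(X, feature_names) {
  X <- as.matrix(as.data.frame(X))
  if (!all(feature_names %in% colnames(X)))
    stop_config("predict_probability: missing feature column(s) %s",
                paste(setdiff(feature_names, colnames(X)), collapse = ", "))
  X[, feature_names, drop = FALSE]
}

#' @export
predict_probability.penalized_fit <- function(model, X) {
  X <- align_columns(X, model$feature_names)
  Xs <- scale(X, center = model$centers, scale = model$scales)
  eta <- model$intercept + drop(Xs %*% model$coefficients)
  1 / (1 + exp(-eta))
}

#' @export
predict_probability.nb_fit <- function(model, X) {
  X <- align_columns(X, model$feature_names)
  loglik <- function(cls) {
    st <- model$by_class[[cls]]
    ll <- rep(log(unname(model$priors[cls])), nrow(X))
    for (j in seq_len(ncol(X)))
      ll <- ll + stats::dnorm(X[, j], st$mean[j], sqrt(st$var[j]), log = TRUE)
    ll
  }
  l0 <- loglik("0")
  l1 <- loglik("1")
  1 / (1 + exp(l0 - l1))
}

#' @export
predict_probability.rf_fit <- function(model, X) {
  X <- as.data.frame(align_columns(X, model$feature_names))
  unname(predict(model$fit, X, type = "prob")[, "1"])
}
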