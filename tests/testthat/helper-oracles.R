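# Independent brute-force oracles for the texture matrices, written as plain
# R loops over voxels so the compiled accumulators are checked against a
# second implementation, plus small fixture builders shared across tests.

random_label_volume <- function(max_dim = 6, ng = 4) {
  d <- sample(3:max_dim, 3, replace = TRUE)
  # 0 = outside ROI, so the ROI is a ragged subset of the grid
  labels <- array(sample(0:ng, prod(d), replace = TRUE,
                         prob = c(0.25, rep(0.75 / ng, ng))), d)
  if (!any(labels > 0)) labels[1, 1, 1] <- 1L
  structure(labels, n_levels = as.integer(ng), degenerate = FALSE,
            class = c("discretized_volume", "array"))
}

as_disc <- function(labels, ng) {
  structure(array(as.integer(labels), dim(labels)),
            n_levels = as.integer(ng), degenerate = FALSE,
            class = c("discretized_volume", "array"))
}

in_bounds <- function(p, d) all(p >= 1) && all(p <= d)

oracle_glcm <- function(labels, ng, dirs) {
  d <- dim(labels)
  out <- array(0, c(ng, ng, nrow(dirs)))
  vox <- which(labels > 0, arr.ind = TRUE)
  for (dir in seq_len(nrow(dirs))) {
    for (r in seq_len(nrow(vox))) {
      p <- vox[r, ]
      q <- p + dirs[dir, ]
      if (!in_bounds(q, d)) next
      b <- labels[q[1], q[2], q[3]]
      if (b == 0) next
      a <- labels[p[1], p[2], p[3]]
      out[a, b, dir] <- out[a, b, dir] + 1
      out[b, a, dir] <- out[b, a, dir] + 1
    }
  }
  out
}

oracle_glcm_correlation <- function(mat) {
  p <- mat / sum(mat)
  ng <- nrow(p)
  mu <- sum(row(p) * p)
  sig2 <- sum((row(p) - mu)^2 * p)
  if (sig2 <= 0) return(0)
  sum(p * (row(p) - mu) * (col(p) - mu)) / sig2
}

oracle_glrlm <- function(labels, ng, dirs) {
  d <- dim(labels)
  runs <- list()
  vox <- which(labels > 0, arr.ind = TRUE)
  for (dir in seq_len(nrow(dirs))) {
    o <- dirs[dir, ]
    for (r in seq_len(nrow(vox))) {
      p <- vox[r, ]
      a <- labels[p[1], p[2], p[3]]
      prev <- p - o
      if (in_bounds(prev, d) && labels[prev[1], prev[2], prev[3]] == a) next
      len <- 0
      q <- p
      while (in_bounds(q, d) && labels[q[1], q[2], q[3]] == a) {
        len <- len + 1
        q <- q + o
      }
      runs[[length(runs) + 1]] <- c(a, len)
    }
  }
  runs <- do.call(rbind, runs)
  maxlen <- max(runs[, 2])
  m <- matrix(0, ng, maxlen)
  for (r in seq_len(nrow(runs))) m[runs[r, 1], runs[r, 2]] <-
      m[runs[r, 1], runs[r, 2]] + 1
  m
}

# 26-connected zones by repeated breadth-first flood fill
oracle_glszm <- function(labels, ng) {
  d <- dim(labels)
  seen <- array(FALSE, d)
  nbrs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nbrs <- nbrs[rowSums(abs(nbrs)) > 0, ]
  zones <- list()
  vox <- which(labels > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(vox))) {
    p <- vox[r, ]
    if (seen[p[1], p[2], p[3]]) next
    lev <- labels[p[1], p[2], p[3]]
    queue <- list(p)
    seen[p[1], p[2], p[3]] <- TRUE
    size <- 0
    while (length(queue)) {
      cur <- queue[[1]]
      queue <- queue[-1]
      size <- size + 1
      for (k in seq_len(nrow(nbrs))) {
        q <- cur + nbrs[k, ]
        if (!in_bounds(q, d)) next
        if (seen[q[1], q[2], q[3]]) next
        if (labels[q[1], q[2], q[3]] != lev) next
        seen[q[1], q[2], q[3]] <- TRUE
        queue[[length(queue) + 1]] <- q
      }
    }
    zones[[length(zones) + 1]] <- c(lev, size)
  }
  zones <- do.call(rbind, zones)
  m <- matrix(0, ng, max(zones[, 2]))
  for (r in seq_len(nrow(zones))) m[zones[r, 1], zones[r, 2]] <-
      m[zones[r, 1], zones[r, 2]] + 1
  m
}

oracle_ngtdm <- function(labels, ng) {
  d <- dim(labels)
  s <- numeric(ng)
  cnt <- integer(ng)
  nbrs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nbrs <- nbrs[rowSums(abs(nbrs)) > 0, ]
  vox <- which(labels > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(vox))) {
    p <- vox[r, ]
    a <- labels[p[1], p[2], p[3]]
    vals <- c()
    for (k in seq_len(nrow(nbrs))) {
      q <- p + nbrs[k, ]
      if (!in_bounds(q, d)) next
      b <- labels[q[1], q[2], q[3]]
      if (b > 0) vals <- c(vals, b)
    }
    cnt[a] <- cnt[a] + 1
    if (length(vals)) s[a] <- s[a] + abs(a - mean(vals))
  }
  list(s = s, n = cnt)
}

# direct separable 3D convolution with mirror extension, used as the
# impulse-response oracle for the wavelet bank
oracle_separable_conv <- function(x, fx, fy, fz, shift) {
  conv1 <- function(v, f) {
    n <- length(v)
    P <- length(f)
    ext <- c(rev(v[1:P]), v, rev(v[(n - P + 1):n]))
    vapply(seq_len(n), function(i) {
      sum(f * ext[i + P + shift - seq_along(f)])
    }, numeric(1))
  }
  d <- dim(x)
  for (j in seq_len(d[2])) for (k in seq_len(d[3]))
    x[, j, k] <- conv1(x[, j, k], fx)
  for (i in seq_len(d[1])) for (k in seq_len(d[3]))
    x[i, , k] <- conv1(x[i, , k], fy)
  for (i in seq_len(d[1])) for (j in seq_len(d[2]))
    x[i, j, ] <- conv1(x[i, j, ], fz)
  x
}

make_sphere <- function(radius_mm, spacing, margin = 4) {
  half <- ceiling(radius_mm / spacing) + margin
  n <- 2 * half + 1
  ax <- (seq_len(n) - half - 1) * spacing
  r2 <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`)
  array(r2 <= radius_mm^2, c(n, n, n))
}

# small deterministic survival fixture used across survival tests
toy_cohort_records <- function(n, seed, beta = 0, x = NULL) {
  withr::with_seed(seed, {
    if (is.null(x)) x <- rnorm(n)
    t_event <- rexp(n, rate = 0.02 * exp(beta * x))
    event <- t_event <= 36
    time <- ifelse(event, pmax(t_event, 0.5), runif(n, 36, 96))
    data.frame(patient_id = sprintf("P%03d", seq_len(n)), x = x,
               ofr_event = event, time_months = time)
  })
}

# clinical + feature tables with a planted informative structure used by
# selection and model tests
planted_feature_cohort <- function(n, seed, beta = 1.3, n_decoys = 7,
                                   decoy_r = 0.9) {
  withr::with_seed(seed, {
    informative <- matrix(rnorm(n * 3), n, 3,
                          dimnames = list(NULL, paste0("inf", 1:3)))
    parents <- sample(1:3, n_decoys, replace = TRUE)
    decoys <- vapply(seq_len(n_decoys), function(j) {
      decoy_r * informative[, parents[j]] +
        sqrt(1 - decoy_r^2) * rnorm(n)
    }, numeric(n))
    colnames(decoys) <- paste0("decoy", seq_len(n_decoys))
    lp <- beta * rowSums(informative) / sqrt(3)
    t_event <- rexp(n, rate = 0.02 * exp(lp))
    event <- t_event <= 36
    records <- data.frame(patient_id = sprintf("P%03d", seq_len(n)),
                          ofr_event = event,
                          time_months = ifelse(event, pmax(t_event, 0.5),
                                               runif(n, 36, 96)),
                          paln = rbinom(n, 1, 0.12) == 1)
    features <- data.frame(patient_id = records$patient_id, informative,
                           decoys, check.names = FALSE)
    list(records = records, features = features)
  })
}
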