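#' Unique 3D lattice directions
#'
#' The 13 direction vectors covering all 26-neighbour displacements up to
#' sign, used by the GLCM and GLRLM accumulators.
#'
#' @param distance Integer step length (default 1).
#' @return Integer matrix 13 x 3 of voxel offsets.
#' @export
lattice_directions <- function(distance = 1L) {
  offs <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  offs <- offs[!(offs$di == 0 & offs$dj == 0 & offs$dk == 0), ]
  canonical <- apply(offs, 1, function(o) {
    first <- o[o != 0][1]
    if (first < 0) -o else o
  })
  dirs <- unique(t(canonical))
  storage.mode(dirs) <- "integer"
  unname(dirs) * as.integer(distance)
}

check_labels <- function(d) {
  if (!inherits(d, "discretized_volume"))
    stop_config("expected a discretized_volume (see discretize())")
  invisible(attr(d, "n_levels"))
}

#' Gray-level co-occurrence matrices
#'
#' Co-occurrences of gray levels at the given voxel distance, accumulated
#' over the 13 unique 3D directions and restricted to voxel pairs that both
#' lie inside the ROI. Each directional matrix is symmetrized.
#'
#' @param d A `discretized_volume` from [discretize()].
#' @param distance Co-occurrence distance in voxels (default 1).
#' @return An `ng x ng x 13` count array (class `glcm`), with the direction
#'   offsets attached as attribute `directions`.
#' @export
build_glcm <- function(d, distance = 1L) {
  ng <- check_labels(d)
  dirs <- lattice_directions(distance)
  counts <- cpp_glcm(as.integer(d), dim(d), ng, dirs)
  structure(counts, directions = dirs, class = c("glcm", "array"))
}

glcm_correlation <- function(mat) {
  tot <- sum(mat)
  if (tot <= 0) return(NA_real_)
  p <- mat / tot
  ng <- nrow(p)
  pi_ <- rowSums(p)
  mu <- sum(seq_len(ng) * pi_)
  sig2 <- sum((seq_len(ng) - mu)^2 * pi_)
  if (sig2 <= 0) return(0)  # constant-ROI convention
  ii <- matrix(seq_len(ng), ng, ng)
  sum(p * (ii - mu) * (t(ii) - mu)) / sig2
}

glcm_contrast <- function(mat) {
  tot <- sum(mat)
  if (tot <= 0) return(NA_real_)
  ng <- nrow(mat)
  ii <- matrix(seq_len(ng), ng, ng)
  sum(mat / tot * (ii - t(ii))^2)
}

#' GLCM summary features
#'
#' `GCorrelation1` is the correlation of the direction-merged matrix;
#' `GCorrelation` is the mean of the per-direction correlations (directions
#' with no in-ROI pair are skipped); `GContrast` is the merged-matrix
#' contrast. A constant ROI yields correlation 0 by convention.
#'
#' @param glcm Output of [build_glcm()].
#' @return Named numeric vector.
#' @export
glcm_features <- function(glcm) {
  merged <- apply(glcm, c(1, 2), sum)
  per_dir <- apply(glcm, 3, glcm_correlation)
  per_dir <- per_dir[!is.na(per_dir)]
  c(GCorrelation1 = glcm_correlation(merged),
    GCorrelation = if (length(per_dir)) mean(per_dir) else 0,
    GContrast = glcm_contrast(merged))
}

#' Gray-level run-length matrix and features
#'
#' Runs of identical gray level counted along each of the 13 directions and
#' pooled into one `ng x max_run` matrix. `RLV` is the run-length variance
#' over the run distribution; `SRE`/`LRE` the short/long run emphases.
#'
#' @inheritParams build_glcm
#' @return `build_glrlm()`: count matrix of class `glrlm`;
#'   `glrlm_features()`: named numeric vector.
#' @export
build_glrlm <- function(d) {
  ng <- check_labels(d)
  m <- cpp_glrlm(as.integer(d), dim(d), ng, lattice_directions(1L))
  keep <- max(which(colSums(m) > 0), 1L)
  structure(m[, seq_len(keep), drop = FALSE], class = c("glrlm", "matrix"))
}

#' @rdname build_glrlm
#' @param glrlm Output of [build_glrlm()].
#' @export
glrlm_features <- function(glrlm) {
  tot <- sum(glrlm)
  p <- glrlm / tot
  j <- col(p)
  mu_j <- sum(p * j)
  c(RLV = sum(p * (j - mu_j)^2),
    SRE = sum(p / j^2),
    LRE = sum(p * j^2))
}

#' Gray-level size-zone matrix and features
#'
#' Zones are 26-connected components of equal gray level; every ROI voxel
#' belongs to exactly one zone. With `p(i, s)` the normalized count of zones
#' of level `i` and size `s`: LZE emphasizes large zones, ZLV/GLV are the
#' zone-size and gray-level variances, LGZE the low gray-level emphasis, and
#' SZLGE/LZLGE/LZHGE the joint size/gray-level emphases.
#'
#' @inheritParams build_glcm
#' @return `build_glszm()`: count matrix `ng x max_size` of class `glszm`;
#'   `glszm_features()`: named numeric vector.
#' @export
build_glszm <- function(d) {
  ng <- check_labels(d)
  m <- cpp_glszm(as.integer(d), dim(d), ng)
  structure(m, class = c("glszm", "matrix"))
}

#' @rdname build_glszm
#' @param glszm Output of [build_glszm()].
#' @export
glszm_features <- function(glszm) {
  tot <- sum(glszm)
  p <- glszm / tot
  i <- row(p)
  s <- col(p)
  mu_s <- sum(p * s)
  mu_i <- sum(p * i)
  c(LZE = sum(p * s^2),
    ZLV = sum(p * (s - mu_s)^2),
    GLV = sum(p * (i - mu_i)^2),
    LGZE = sum(p / i^2),
    SZLGE = sum(p / (i^2 * s^2)),
    LZLGE = sum(p * s^2 / i^2),
    LZHGE = sum(p * s^2 * i^2))
}

#' Neighbourhood gray-tone difference matrix and features
#'
#' For each gray level `i`, `s_i` sums the absolute difference between `i`
#' and the mean gray level of the 26-neighbourhood (in-ROI neighbours only)
#' over all ROI voxels of level `i`; `p_i` is the level frequency.
#' `Busyness` = sum(p_i s_i) / sum_ij |i p_i - j p_j| over occurring levels,
#' 0 by convention for a constant ROI; `Coarseness` = 1 / sum(p_i s_i)
#' (capped at 1e6 when the denominator vanishes).
#'
#' @inheritParams build_glcm
#' @return `build_ngtdm()`: list with `s`, `n`, `p` per level (class
#'   `ngtdm`); `ngtdm_features()`: named numeric vector.
#' @export
build_ngtdm <- function(d) {
  ng <- check_labels(d)
  res <- cpp_ngtdm(as.integer(d), dim(d), ng)
  res$p <- res$n / sum(res$n)
  class(res) <- "ngtdm"
  res
}

#' @rdname build_ngtdm
#' @param ngtdm Output of [build_ngtdm()].
#' @export
ngtdm_features <- function(ngtdm) {
  occ <- which(ngtdm$n > 0)
  p <- ngtdm$p[occ]
  s <- ngtdm$s[occ]
  lev <- occ
  num <- sum(p * s)
  denom <- sum(abs(outer(lev * p, lev * p, "-")))
  busy <- if (denom <= 0) 0 else num / denom
  coarse <- if (num <= 0) 1e6 else 1 / num
  c(Busyness = busy, Coarseness = coarse)
}
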