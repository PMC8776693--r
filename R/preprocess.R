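#' Resample an image/mask pair to an isotropic grid
#'
#' Both volumes are resampled onto a common isotropic grid (default
#' 2 x 2 x 2 mm, the working resolution of the feature pipeline) covering the
#' original extent. The image is interpolated trilinearly; the mask by
#' nearest neighbour so it stays strictly binary.
#'
#' @param img An [image_volume].
#' @param mask The companion [roi_mask] on the same grid.
#' @param target_mm Target isotropic voxel size in mm (default 2).
#' @return A list with resampled `img` and `mask`.
#' @export
resample_isotropic <- function(img, mask, target_mm = 2.0) {
  check_same_grid(img, mask)
  sp <- img$spacing_mm
  if (max(abs(sp - target_mm)) < 1e-9)
    return(list(img = img, mask = mask))
  d <- dim(img$values)
  extent <- d * sp
  nd <- pmax(2L, as.integer(ceiling(extent / target_mm)))
  # output voxel centers in input (1-based, fractional) index space
  ax <- lapply(1:3, function(a) ((seq_len(nd[a]) - 1) * target_mm) / sp[a] + 1)
  grid <- list(
    x = array(rep(ax[[1]], times = nd[2] * nd[3]), nd),
    y = array(rep(rep(ax[[2]], each = nd[1]), times = nd[3]), nd),
    z = array(rep(ax[[3]], each = nd[1] * nd[2]), nd))
  new_img <- trilinear_gather(img$values, grid$x, grid$y, grid$z)
  nn <- function(v, n) pmin(pmax(round(v), 1), n)
  idx <- cbind(as.vector(nn(grid$x, d[1])), as.vector(nn(grid$y, d[2])),
               as.vector(nn(grid$z, d[3])))
  new_mask <- array(mask$values[idx], nd)
  if (!any(new_mask))
    stop_config("resample_isotropic: ROI empty after resampling (degenerate ROI)")
  list(img = image_volume(new_img, spacing_mm = rep(target_mm, 3),
                          origin_mm = img$origin_mm),
       mask = roi_mask(new_mask, spacing_mm = rep(target_mm, 3),
                       origin_mm = img$origin_mm))
}

# Vectorized trilinear interpolation at fractional (1-based) index positions,
# clamped to the grid so border queries use edge values.
trilinear_gather <- function(vals, xi, yi, zi) {
  d <- dim(vals)
  out_dim <- dim(xi)
  xi <- pmin(pmax(as.vector(xi), 1), d[1])
  yi <- pmin(pmax(as.vector(yi), 1), d[2])
  zi <- pmin(pmax(as.vector(zi), 1), d[3])
  x0 <- pmin(floor(xi), d[1] - 1); y0 <- pmin(floor(yi), d[2] - 1)
  z0 <- pmin(floor(zi), d[3] - 1)
  fx <- xi - x0; fy <- yi - y0; fz <- zi - z0
  at <- function(i, j, k) vals[cbind(i, j, k)]
  v <- at(x0, y0, z0) * (1 - fx) * (1 - fy) * (1 - fz) +
    at(x0 + 1, y0, z0) * fx * (1 - fy) * (1 - fz) +
    at(x0, y0 + 1, z0) * (1 - fx) * fy * (1 - fz) +
    at(x0 + 1, y0 + 1, z0) * fx * fy * (1 - fz) +
    at(x0, y0, z0 + 1) * (1 - fx) * (1 - fy) * fz +
    at(x0 + 1, y0, z0 + 1) * fx * (1 - fy) * fz +
    at(x0, y0 + 1, z0 + 1) * (1 - fx) * fy * fz +
    at(x0 + 1, y0 + 1, z0 + 1) * fx * fy * fz
  array(v, out_dim)
}

#' ROI intensity normalization
#'
#' Two normalizations of ROI voxel intensities, both computed from
#' ROI-restricted statistics and both exactly invariant to positive affine
#' transforms of the raw intensities. Voxels outside the ROI are set to 0.
#'
#' `normalize_minmax()` maps the ROI range to \[0, 1\];
#' `normalize_zscore()` centers to mean 0 and scales to unit population
#' standard deviation.
#'
#' @param img An [image_volume].
#' @param mask The companion [roi_mask].
#' @return A normalized [image_volume] on the same grid.
#' @export
normalize_minmax <- function(img, mask) {
  check_same_grid(img, mask)
  v <- img$values[mask$values]
  rng <- range(v)
  if (diff(rng) <= 0)
    stop_config("normalize_minmax: constant ROI intensities (degenerate)")
  out <- array(0, dim(img$values))
  out[mask$values] <- (v - rng[1]) / diff(rng)
  image_volume(out, spacing_mm = img$spacing_mm, origin_mm = img$origin_mm)
}

#' @rdname normalize_minmax
#' @export
normalize_zscore <- function(img, mask) {
  check_same_grid(img, mask)
  v <- img$values[mask$values]
  s <- pop_sd(v)
  if (s <= 0)
    stop_config("normalize_zscore: zero ROI standard deviation (degenerate)")
  out <- array(0, dim(img$values))
  out[mask$values] <- (v - mean(v)) / s
  image_volume(out, spacing_mm = img$spacing_mm, origin_mm = img$origin_mm)
}

#' Discretize ROI intensities into gray levels
#'
#' Equal-width binning of ROI intensities between the ROI minimum and maximum
#' into `n_levels` gray levels: level = min(floor((v - min) / (max - min) *
#' Ng) + 1, Ng). Voxels outside the ROI get level 0. A constant ROI yields
#' all level 1 with attribute `degenerate = TRUE`.
#'
#' @param img An [image_volume] (typically a normalized image or wavelet
#'   band).
#' @param mask The companion [roi_mask].
#' @param n_levels Number of gray levels Ng (>= 2), default 32.
#' @return Integer array of the image dimensions with class
#'   `discretized_volume` and attributes `n_levels` and `degenerate`.
#' @export
discretize <- function(img, mask, n_levels = 32L) {
  check_same_grid(img, mask)
  n_levels <- as.integer(n_levels)
  if (is.na(n_levels) || n_levels < 2L)
    stop_config("discretize: n_levels must be >= 2")
  v <- img$values[mask$values]
  rng <- range(v)
  labels <- array(0L, dim(img$values))
  degenerate <- diff(rng) <= 0
  if (degenerate) {
    labels[mask$values] <- 1L
  } else {
    lev <- pmin(floor((v - rng[1]) / diff(rng) * n_levels) + 1, n_levels)
    labels[mask$values] <- as.integer(lev)
  }
  structure(labels, n_levels = n_levels, degenerate = degenerate,
            class = c("discretized_volume", "array"))
}
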