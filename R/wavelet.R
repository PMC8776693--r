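#' Wavelet filter coefficients
#'
#' Analysis/synthesis filter taps for the orthogonal wavelets supported by
#' the undecimated 3D transform. The default, Coiflet-1, matches the filter
#' used throughout the radiomics toolkit lineage this pipeline follows.
#'
#' @param name Wavelet family: `"coif1"` or `"haar"`.
#' @return List with `dec_lo`, `dec_hi`, `rec_lo`, `rec_hi` numeric vectors.
#' @export
wavelet_filters <- function(name = "coif1") {
  name <- match.arg(name, c("coif1", "haar"))
  dec_lo <- switch(name,
    coif1 = c(-0.015655728135791993, -0.07273261951252645,
              0.38486484686485778, 0.85257202021160039,
              0.33789766245748182, -0.07273261951252645),
    haar = c(1, 1) / sqrt(2))
  L <- length(dec_lo)
  # quadrature mirror: g[k] = (-1)^k h[L+1-k]
  dec_hi <- rev(dec_lo) * (-1)^(seq_len(L))
  list(dec_lo = dec_lo, dec_hi = dec_hi,
       rec_lo = rev(dec_lo), rec_hi = rev(dec_hi))
}

#' Band codes of the 9-image wavelet bank
#'
#' `ROI` is the unfiltered original image; the other eight codes name the
#' per-axis low/high-pass filters in axis order (x, y, z).
#'
#' @return Character vector of the 9 band codes.
#' @export
band_codes <- function() {
  c("ROI", "LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")
}

# 1D filtering along one axis of a 3D array. The signal is extended by the
# filter length on both sides (half-sample mirror for "symmetric", wrap for
# "periodic"), convolved, and cropped back to the original grid so the
# transform is undecimated and every band shares the input grid.
conv_axis <- function(arr, f, axis, boundary = "symmetric",
                      shift = length(f) %/% 2 + 1L) {
  d <- dim(arr)
  P <- length(f)
  if (d[axis] < P)
    stop_config("wavelet: extent along axis %d (%d) smaller than filter (%d)",
                axis, d[axis], P)
  perm <- switch(axis, `1` = c(1L, 2L, 3L), `2` = c(2L, 1L, 3L),
                 `3` = c(3L, 1L, 2L))
  a <- if (axis == 1L) arr else aperm(arr, perm)
  da <- dim(a)
  m <- matrix(a, da[1], da[2] * da[3])
  n <- da[1]
  if (boundary == "symmetric") {
    top <- m[P:1, , drop = FALSE]
    bottom <- m[n:(n - P + 1), , drop = FALSE]
  } else if (boundary == "periodic") {
    top <- m[(n - P + 1):n, , drop = FALSE]
    bottom <- m[1:P, , drop = FALSE]
  } else stop_config("wavelet: unknown boundary '%s'", boundary)
  ext <- rbind(top, m, bottom)
  # out[i] = sum_k f[k] * x[i - k + shift], via shifted-block accumulation
  res <- matrix(0, n, ncol(ext))
  for (k in seq_len(P)) {
    st <- P + shift - k + 1L
    res <- res + f[k] * ext[st:(st + n - 1L), , drop = FALSE]
  }
  out <- array(res, da)
  if (axis == 1L) out else aperm(out, order(perm))
}

#' Undecimated 3D wavelet decomposition
#'
#' Single-level stationary (undecimated) separable 3D wavelet transform. The
#' eight sub-bands are labeled by the per-axis filter, L = low-pass,
#' H = high-pass, in axis order (x, y, z); all sub-bands stay on the input
#' grid so the same ROI mask applies without resampling. The original image
#' is included under band code `ROI`, giving the nine-image bank the feature
#' extractor iterates over.
#'
#' Boundary handling defaults to mirror (symmetric) padding, which avoids
#' edge ringing in small ROIs; `"periodic"` extension is also available and
#' gives exact filter-bank reconstruction via [wavelet_reconstruct()].
#'
#' @param img An [image_volume].
#' @param wavelet Wavelet family, see [wavelet_filters()].
#' @param boundary `"symmetric"` (default) or `"periodic"`.
#' @return A named list of 9 [image_volume] objects (class `wavelet_bank`).
#' @export
wavelet_decompose <- function(img, wavelet = "coif1",
                              boundary = "symmetric") {
  flt <- wavelet_filters(wavelet)
  x <- img$values
  fs <- list(L = flt$dec_lo, H = flt$dec_hi)
  lev1 <- lapply(fs, function(f) conv_axis(x, f, 1L, boundary))
  lev2 <- list()
  for (n1 in names(lev1))
    for (n2 in names(fs))
      lev2[[paste0(n1, n2)]] <- conv_axis(lev1[[n1]], fs[[n2]], 2L, boundary)
  bank <- list(ROI = img)
  for (n12 in names(lev2))
    for (n3 in names(fs))
      bank[[paste0(n12, n3)]] <- image_volume(
        conv_axis(lev2[[n12]], fs[[n3]], 3L, boundary),
        spacing_mm = img$spacing_mm, origin_mm = img$origin_mm)
  bank <- bank[band_codes()]
  class(bank) <- "wavelet_bank"
  bank
}

#' Reconstruct the input from an undecimated wavelet bank
#'
#' Inverse of the single-level stationary transform: each axis pair of
#' (low, high) bands is synthesis-filtered with the time-reversed filters and
#' averaged. Reconstruction is exact (to floating point) when the bank was
#' computed with `boundary = "periodic"`; with mirror padding it is exact
#' away from the volume boundary.
#'
#' @param bank A `wavelet_bank` from [wavelet_decompose()].
#' @inheritParams wavelet_decompose
#' @return An [image_volume] approximating the original input.
#' @export
wavelet_reconstruct <- function(bank, wavelet = "coif1",
                                boundary = "periodic") {
  flt <- wavelet_filters(wavelet)
  L <- length(flt$dec_lo)
  s2 <- L + 1L - (L %/% 2 + 1L)  # mirror of the analysis alignment
  merge_axis <- function(a, d, axis) {
    0.5 * (conv_axis(a, flt$rec_lo, axis, boundary, shift = s2) +
             conv_axis(d, flt$rec_hi, axis, boundary, shift = s2))
  }
  sub <- lapply(bank[setdiff(band_codes(), "ROI")], function(b) b$values)
  # collapse z, then y, then x
  for (axis in c(3L, 2L, 1L)) {
    nms <- unique(substr(names(sub), 1L, axis - 1L))
    merged <- list()
    for (nm in if (axis == 1L) "" else nms) {
      merged[[if (nm == "") "x" else nm]] <-
        merge_axis(sub[[paste0(nm, "L")]], sub[[paste0(nm, "H")]], axis)
    }
    sub <- merged
  }
  image_volume(sub[["x"]], spacing_mm = bank$ROI$spacing_mm,
               origin_mm = bank$ROI$origin_mm)
}
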