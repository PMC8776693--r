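#' Default feature registry
#'
#' The registry makes the feature composition explicit and auditable: it maps
#' each feature family to the statistics computed per wavelet band. Feature
#' names follow the `<band><FeatureName>` convention (e.g. `HHHRLV`,
#' `ROIBusyness`), with shape features band-independent and unprefixed.
#' The default registry computes, per band: 4 histogram features, 3 GLCM,
#' 3 GLRLM, 7 GLSZM and 2 NGTDM statistics, over the 9-image bank (171
#' features), plus 4 shape features — 175 features per image sequence.
#'
#' @param histogram,glcm,glrlm,glszm,ngtdm,shape Character vectors selecting
#'   the statistics per family; set to `character(0)` to disable a family.
#' @return A list of class `feature_registry`.
#' @export
feature_registry <- function(
    histogram = c("Mean", "Variance", "Skewness", "Energy"),
    glcm = c("GCorrelation1", "GCorrelation", "GContrast"),
    glrlm = c("RLV", "SRE", "LRE"),
    glszm = c("LZE", "ZLV", "GLV", "LGZE", "SZLGE", "LZLGE", "LZHGE"),
    ngtdm = c("Busyness", "Coarseness"),
    shape = c("Volume_ml", "SurfaceArea_mm2", "Max3Ddiameter",
              "SpheDisproportion")) {
  structure(list(histogram = histogram, glcm = glcm, glrlm = glrlm,
                 glszm = glszm, ngtdm = ngtdm, shape = shape),
            class = "feature_registry")
}

#' @rdname feature_registry
#' @param registry A `feature_registry`.
#' @export
registry_feature_names <- function(registry = feature_registry()) {
  per_band <- unlist(registry[c("histogram", "glcm", "glrlm", "glszm",
                                "ngtdm")], use.names = FALSE)
  c(as.vector(t(outer(band_codes(), per_band, paste0))), registry$shape)
}

#' Extract the full radiomics feature vector for one patient
#'
#' Runs the whole per-patient pipeline: resample the image/mask pair to the
#' isotropic working grid, normalize ROI intensities, build the 9-image
#' undecimated wavelet bank, then per band discretize the ROI and compute
#' histogram and texture statistics, plus the global shape features. Bands
#' with constant ROI intensity fall back to the documented degeneracy
#' conventions and are recorded in the `flags` attribute.
#'
#' @param img An [image_volume].
#' @param mask The companion [roi_mask].
#' @param registry A [feature_registry()].
#' @param normalization `"zscore"` (default) or `"minmax"`.
#' @param n_levels Gray levels for discretization (default 32).
#' @param target_mm Isotropic resampling target (default 2 mm).
#' @param wavelet,boundary Passed to [wavelet_decompose()].
#' @return Named numeric vector of features (attribute `flags` lists
#'   degenerate bands).
#' @export
extract_features <- function(img, mask, registry = feature_registry(),
                             normalization = c("zscore", "minmax"),
                             n_levels = 32L, target_mm = 2.0,
                             wavelet = "coif1", boundary = "symmetric") {
  normalization <- match.arg(normalization)
  rs <- resample_isotropic(img, mask, target_mm)
  norm <- switch(normalization,
                 zscore = normalize_zscore(rs$img, rs$mask),
                 minmax = normalize_minmax(rs$img, rs$mask))
  bank <- wavelet_decompose(norm, wavelet = wavelet, boundary = boundary)
  roi <- rs$mask
  out <- numeric(0)
  flags <- character(0)
  for (band in band_codes()) {
    vals <- bank[[band]]$values[roi$values]
    feats <- numeric(0)
    if (length(registry$histogram)) {
      h <- histogram_features(vals)
      if (isTRUE(attr(h, "degenerate"))) flags <- c(flags, band)
      feats <- c(feats, h[registry$histogram])
    }
    need_tex <- length(registry$glcm) || length(registry$glrlm) ||
      length(registry$glszm) || length(registry$ngtdm)
    if (need_tex) {
      disc <- discretize(bank[[band]], roi, n_levels = n_levels)
      if (isTRUE(attr(disc, "degenerate"))) flags <- unique(c(flags, band))
      if (length(registry$glcm))
        feats <- c(feats, glcm_features(build_glcm(disc))[registry$glcm])
      if (length(registry$glrlm))
        feats <- c(feats, glrlm_features(build_glrlm(disc))[registry$glrlm])
      if (length(registry$glszm))
        feats <- c(feats, glszm_features(build_glszm(disc))[registry$glszm])
      if (length(registry$ngtdm))
        feats <- c(feats, ngtdm_features(build_ngtdm(disc))[registry$ngtdm])
    }
    names(feats) <- paste0(band, names(feats))
    out <- c(out, feats)
  }
  if (length(registry$shape))
    out <- c(out, shape_features(roi)[registry$shape])
  structure(out, flags = unique(flags))
}

#' Extract features for a whole cohort
#'
#' Applies [extract_features()] to every patient of a simulated or loaded
#' cohort and assembles the patients-by-features table.
#'
#' @param cohort A cohort list as returned by [simulate_cohort()] or
#'   [read_cohort()]: elements `records`, `images`, `masks`.
#' @inheritParams extract_features
#' @return A `data.frame` with `patient_id` and one column per feature.
#' @export
extract_cohort_features <- function(cohort, registry = feature_registry(),
                                    normalization = "zscore",
                                    n_levels = 32L, target_mm = 2.0) {
  ids <- cohort$records$patient_id
  rows <- lapply(seq_along(ids), function(i) {
    extract_features(cohort$images[[i]], cohort$masks[[i]],
                     registry = registry, normalization = normalization,
                     n_levels = n_levels, target_mm = target_mm)
  })
  tab <- as.data.frame(do.call(rbind, rows))
  data.frame(patient_id = ids, tab, check.names = FALSE,
             stringsAsFactors = FALSE)
}
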