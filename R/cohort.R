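#' Configuration of the synthetic phantom cohort
#'
#' Defines the statistical structure of the simulated multi-institutional
#' cohort the pipeline is exercised on. The defaults reproduce the published
#' contingency structure of the 180-patient study population: 21/180
#' para-aortic lymph node (PALN) positive patients, out-of-field recurrence
#' (OFR) within 3 years in 12/21 PALN-positive and 26/159 PALN-negative
#' patients, 13 institutions of which three contribute more than 20 patients
#' and two ("H", "J") contribute no events.
#'
#' Tumor volumes are drawn log-uniformly over `volume_range_ml`; the default
#' upper bound (30 ml, near the cohort median of 33 ml) keeps phantoms well
#' inside the default 64 mm image extent. `texture_effect_size` controls how
#' strongly the outcome modulates intratumoral texture: the correlation
#' length of the interior Gaussian random field is multiplied by
#' `1 + texture_effect_size` and its standard deviation by
#' `1 + 0.25 * texture_effect_size` for patients who develop OFR; 0 yields
#' label-free images.
#'
#' @param n_patients Cohort size (default 180).
#' @param prevalence_paln P(PALN positive), default 21/180.
#' @param p_ofr_given_paln_pos,p_ofr_given_paln_neg Conditional OFR
#'   probabilities, defaults 12/21 and 26/159.
#' @param institution_sizes Named integer vector of per-institution patient
#'   counts (rescaled proportionally when `n_patients` differs from their
#'   sum).
#' @param institutions_without_events Institutions that never receive an
#'   event patient.
#' @param texture_effect_size Dimensionless effect size >= 0.
#' @param image_shape,voxel_spacing_mm Phantom grid (default 32^3 at 2 mm).
#' @param noise_sd Additive white-noise SD in intensity units.
#' @param volume_range_ml Range tumor volumes are drawn from.
#' @param seed Integer seed governing the whole cohort; per-patient streams
#'   are derived by hashing `(seed, patient_id)` so cohorts are extensible
#'   without reshuffling.
#' @param ... Advanced generator parameters: `tumor_level` (100),
#'   `background_level` (20), `texture_sd` (15), `texture_corr_base`
#'   (0.7 voxels), `inst_scale_sd` (0.08), `inst_offset_sd` (3),
#'   `inst_noise_sd` (2), `age_range` (29-80), `institution_effects`
#'   (optional data.frame with columns institution/scale/offset overriding
#'   the seed-derived affine distortions).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 180L,
                          prevalence_paln = 21 / 180,
                          p_ofr_given_paln_pos = 12 / 21,
                          p_ofr_given_paln_neg = 26 / 159,
                          institution_sizes = c(A = 9, B = 8, C = 12, D = 10,
                                                E = 30, F = 14, G = 13, H = 6,
                                                I = 15, J = 4, K = 11, L = 26,
                                                M = 22),
                          institutions_without_events = c("H", "J"),
                          texture_effect_size = 1,
                          image_shape = c(32L, 32L, 32L),
                          voxel_spacing_mm = c(2, 2, 2),
                          noise_sd = 2,
                          volume_range_ml = c(3, 30),
                          seed = 1L, ...) {
  extra <- list(...)
  defaults <- list(tumor_level = 100, background_level = 20, texture_sd = 15,
                   texture_corr_base = 0.7, inst_scale_sd = 0.08,
                   inst_offset_sd = 3, inst_noise_sd = 2,
                   age_range = c(29, 80), institution_effects = NULL)
  unknown <- setdiff(names(extra), names(defaults))
  if (length(unknown))
    stop_config("cohort_config: unknown parameter(s) %s",
                paste(unknown, collapse = ", "))
  for (p in c(prevalence_paln, p_ofr_given_paln_pos, p_ofr_given_paln_neg))
    if (!is_probability(p))
      stop_config("cohort_config: probabilities must lie in [0, 1]")
  if (n_patients < 0) stop_config("cohort_config: n_patients must be >= 0")
  if (is.null(names(institution_sizes)) || any(institution_sizes < 0))
    stop_config("cohort_config: institution_sizes must be a named nonnegative vector")
  if (!all(institutions_without_events %in% names(institution_sizes)))
    stop_config("cohort_config: institutions_without_events must name configured institutions")
  if (texture_effect_size < 0)
    stop_config("cohort_config: texture_effect_size must be >= 0")
  cfg <- c(list(n_patients = as.integer(n_patients),
                prevalence_paln = prevalence_paln,
                p_ofr_given_paln_pos = p_ofr_given_paln_pos,
                p_ofr_given_paln_neg = p_ofr_given_paln_neg,
                institution_sizes = institution_sizes,
                n_institutions = length(institution_sizes),
                institutions_without_events = institutions_without_events,
                texture_effect_size = texture_effect_size,
                image_shape = as.integer(image_shape),
                voxel_spacing_mm = as.numeric(voxel_spacing_mm),
                noise_sd = noise_sd,
                volume_range_ml = volume_range_ml,
                seed = as.integer(seed)),
           utils::modifyList(defaults, extra))
  class(cfg) <- "cohort_config"
  cfg
}

# proportional allocation of n slots to the configured institution sizes
# (largest-remainder rounding)
institution_slots <- function(config) {
  sizes <- config$institution_sizes
  n <- config$n_patients
  if (n == 0) return(character(0))
  target <- sizes / sum(sizes) * n
  base <- floor(target)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(target - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  rep(names(sizes), base)
}

#' Sample the clinical covariate table
#'
#' Draws the per-patient clinical records: PALN status Bernoulli with the
#' configured prevalence, the OFR event from the conditional probabilities,
#' event times uniform on (1, 36) months and non-event follow-up uniform on
#' (36, 96), and the remaining covariates from ranges consistent with the
#' published cohort (age 29-80, performance status 0-2, histology, pelvic
#' and common iliac nodal status, treatment doses). Institutions are
#' allocated with the configured sizes; institutions listed in
#' `institutions_without_events` receive only event-free patients.
#'
#' @param config A [cohort_config()].
#' @return `data.frame` of clinical records, one row per patient.
#' @export
sample_clinical_table <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  cols <- c("patient_id", "age", "performance_status", "histology_class",
            "tumor_max_diameter", "tumor_volume", "pelvic_ln_class",
            "common_iliac_ln", "paln", "wp_dose", "boost_to_ln",
            "bt_pointA_dose", "chemo_class", "institution", "ofr_event",
            "time_months")
  if (n == 0) {
    empty <- as.data.frame(setNames(rep(list(logical(0)), length(cols)),
                                    cols))
    return(empty)
  }
  withr::with_seed(derive_seed(config$seed, "clinical"), {
    paln <- rbinom(n, 1, config$prevalence_paln) == 1
    p_ofr <- ifelse(paln, config$p_ofr_given_paln_pos,
                    config$p_ofr_given_paln_neg)
    ofr <- rbinom(n, 1, p_ofr) == 1
    time_months <- ifelse(ofr, runif(n, 1, 36), runif(n, 36, 96))
    vol <- exp(runif(n, log(config$volume_range_ml[1]),
                     log(config$volume_range_ml[2])))
    r_cm <- (3 * vol / (4 * pi))^(1 / 3)
    diam <- 2 * r_cm * runif(n, 1.05, 1.35)
    slots <- institution_slots(config)
    allowed <- !(slots %in% config$institutions_without_events)
    inst <- character(n)
    ev_idx <- which(ofr)
    if (length(ev_idx) > sum(allowed))
      stop_config("sample_clinical_table: not enough capacity outside zero-event institutions for %d events",
                  length(ev_idx))
    resample <- function(x, k = length(x)) x[sample.int(length(x), k)]
    ev_slots <- resample(which(allowed), length(ev_idx))
    inst[ev_idx] <- slots[ev_slots]
    rest <- setdiff(seq_len(n), ev_slots)
    inst[setdiff(seq_len(n), ev_idx)] <- slots[resample(rest)]
    data.frame(
      patient_id = sprintf("P%03d", seq_len(n)),
      age = round(runif(n, config$age_range[1], config$age_range[2])),
      performance_status = sample(0:2, n, replace = TRUE,
                                  prob = c(132, 45, 3) / 180),
      histology_class = sample(c("scc", "other"), n, replace = TRUE,
                               prob = c(167, 13) / 180),
      tumor_max_diameter = round(diam, 1),
      tumor_volume = round(vol, 1),
      pelvic_ln_class = sample(c("0", "1-2", ">=3"), n, replace = TRUE,
                               prob = c(112, 49, 19) / 180),
      common_iliac_ln = rbinom(n, 1, 19 / 180) == 1,
      paln = paln,
      wp_dose = round(runif(n, 45, 60.6), 1),
      boost_to_ln = rbinom(n, 1, 51 / 180) == 1,
      bt_pointA_dose = round(runif(n, 12, 36.1), 1),
      chemo_class = sample(c("weekly_cddp", "daily_cddp", "other"), n,
                           replace = TRUE, prob = c(133, 15, 32) / 180),
      institution = inst,
      ofr_event = ofr,
      time_months = time_months,
      stringsAsFactors = FALSE)
  })
}

# separable Gaussian smoothing of a 3D array (sigma in voxels)
gauss_smooth3 <- function(arr, sigma) {
  if (sigma < 0.05) return(arr)
  half <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  k <- k / sum(k)
  s <- half + 1L
  for (axis in 1:3) arr <- conv_axis(arr, k, axis, "symmetric", shift = s)
  arr
}

#' Generate one phantom tumor volume
#'
#' Builds the synthetic image/mask pair for one clinical record: an
#' ellipsoidal mask whose rasterized volume matches `record$tumor_volume`
#' (axis ratios drawn per patient), interior intensity at the tumor base
#' level plus a Gaussian random field whose correlation length and variance
#' shift with `texture_effect_size` when the patient develops OFR, a distinct
#' background base level, and additive white noise. Deterministic given
#' `(config$seed, record$patient_id)`.
#'
#' @param record One row of the clinical table.
#' @param config A [cohort_config()].
#' @return List with `image` ([image_volume]) and `mask` ([roi_mask]).
#' @export
generate_phantom <- function(record, config) {
  stopifnot(inherits(config, "cohort_config"))
  dims <- config$image_shape
  sp <- config$voxel_spacing_mm
  withr::with_seed(derive_seed(config$seed,
                               paste0("phantom:", record$patient_id)), {
    v_mm3 <- record$tumor_volume * 1000
    r <- (3 * v_mm3 / (4 * pi))^(1 / 3)
    u <- runif(2, 0.85, 1.15)
    semi <- c(r * u[1], r * u[2], r / prod(u))
    extent <- dims * sp
    if (any(2 * semi > extent - 4 * sp))
      stop_config("generate_phantom: tumor of %.1f ml exceeds the image extent",
                  record$tumor_volume)
    centre <- extent / 2
    ax <- lapply(1:3, function(a) (seq_len(dims[a]) - 0.5) * sp[a])
    q <- lapply(1:3, function(a) ((ax[[a]] - centre[a]) / semi[a])^2)
    mask <- (array(rep(q[[1]], times = dims[2] * dims[3]), dims) +
               array(rep(rep(q[[2]], each = dims[1]), times = dims[3]), dims) +
               array(rep(q[[3]], each = dims[1] * dims[2]), dims)) <= 1
    ofr <- isTRUE(record$ofr_event)
    eff <- config$texture_effect_size
    sigma <- config$texture_corr_base * (1 + if (ofr) eff else 0)
    tex_sd <- config$texture_sd * (1 + if (ofr) 0.25 * eff else 0)
    field <- gauss_smooth3(array(rnorm(prod(dims)), dims), sigma)
    field <- (field - mean(field)) / sd(field) * tex_sd
    vals <- array(config$background_level, dims)
    vals[mask] <- config$tumor_level + field[mask]
    if (config$noise_sd > 0)
      vals <- vals + array(rnorm(prod(dims), 0, config$noise_sd), dims)
    list(image = image_volume(vals, spacing_mm = sp),
         mask = roi_mask(mask, spacing_mm = sp))
  })
}

#' Apply an institution-specific intensity distortion
#'
#' Affine intensity distortion (scale, offset) with institution-specific
#' parameters, plus additive scanner noise, emulating inter-institutional
#' differences in imaging protocol and hardware. The mask is unaffected.
#' Scale and offset are derived deterministically from the cohort seed (or
#' taken from `config$institution_effects` when supplied); the additive
#' noise uses the caller's RNG stream.
#'
#' @param img An [image_volume].
#' @param institution Institution id known to the config.
#' @param config A [cohort_config()].
#' @return The distorted [image_volume].
#' @export
apply_institution_effect <- function(img, institution, config) {
  stopifnot(inherits(config, "cohort_config"))
  if (!institution %in% names(config$institution_sizes))
    stop_config("apply_institution_effect: unknown institution '%s'",
                institution)
  eff <- config$institution_effects
  if (!is.null(eff) && institution %in% eff$institution) {
    row <- eff[eff$institution == institution, ][1, ]
    scale <- row$scale
    offset <- row$offset
  } else {
    pars <- withr::with_seed(derive_seed(config$seed,
                                         paste0("inst:", institution)), {
      c(exp(rnorm(1, 0, config$inst_scale_sd)),
        rnorm(1, 0, config$inst_offset_sd))
    })
    scale <- pars[1]
    offset <- pars[2]
  }
  vals <- img$values * scale + offset
  if (config$inst_noise_sd > 0)
    vals <- vals + array(rnorm(length(vals), 0, config$inst_noise_sd),
                         dim(vals))
  image_volume(vals, spacing_mm = img$spacing_mm, origin_mm = img$origin_mm)
}

#' Simulate a complete phantom cohort
#'
#' Samples the clinical table, generates each patient's phantom and applies
#' that patient's institution effect. The result holds everything the
#' downstream feature extraction and modelling steps need.
#'
#' @param config A [cohort_config()].
#' @return List of class `phantom_cohort` with `records`, `images`, `masks`,
#'   `config`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  records <- sample_clinical_table(config)
  images <- vector("list", nrow(records))
  masks <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    ph <- generate_phantom(records[i, ], config)
    img <- withr::with_seed(
      derive_seed(config$seed, paste0("instnoise:", records$patient_id[i])),
      apply_institution_effect(ph$image, records$institution[i], config))
    images[[i]] <- img
    masks[[i]] <- ph$mask
  }
  names(images) <- names(masks) <- records$patient_id
  structure(list(records = records, images = images, masks = masks,
                 config = config),
            class = "phantom_cohort")
}

#' Write / read a cohort on disk
#'
#' `write_cohort()` writes per-patient NIfTI image and mask files, the
#' clinical table as CSV and a JSON manifest recording the seed and
#' configuration; `read_cohort()` loads it all back.
#'
#' @param cohort A `phantom_cohort`.
#' @param out_dir Output directory (created if needed).
#' @return `write_cohort()` returns the manifest (invisibly);
#'   `read_cohort()` a `phantom_cohort` (without the full config object,
#'   which is echoed in `manifest`).
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop_config("write_cohort: cannot create %s", out_dir)
  ids <- cohort$records$patient_id
  files <- lapply(ids, function(id) {
    imgf <- file.path(out_dir, paste0(id, "_image.nii.gz"))
    mskf <- file.path(out_dir, paste0(id, "_mask.nii.gz"))
    write_volume(cohort$images[[id]], imgf)
    write_volume(cohort$masks[[id]], mskf)
    list(patient_id = id, image = basename(imgf), mask = basename(mskf))
  })
  csv <- file.path(out_dir, "clinical.csv")
  write.csv(cohort$records, csv, row.names = FALSE)
  cfg <- cohort$config
  cfg$institution_sizes <- as.list(cfg$institution_sizes)
  manifest <- list(seed = cohort$config$seed, n_patients = length(ids),
                   clinical = basename(csv), patients = files,
                   config = unclass(cfg))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' @rdname write_cohort
#' @param dir Directory written by [write_cohort()].
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  records <- read.csv(file.path(dir, manifest$clinical),
                      stringsAsFactors = FALSE)
  images <- list()
  masks <- list()
  for (p in manifest$patients) {
    images[[p$patient_id]] <- read_volume(file.path(dir, p$image))
    masks[[p$patient_id]] <- read_mask(file.path(dir, p$mask))
  }
  structure(list(records = records, images = images, masks = masks,
                 manifest = manifest),
            class = "phantom_cohort")
}

#' Contingency summary of PALN status versus OFR
#'
#' Cross-tabulates para-aortic nodal status against the 3-year OFR event and
#' reports the percentages the study population is characterized by.
#'
#' @param records Clinical table with columns `paln` and `ofr_event`.
#' @return List with counts and percentages (`ofr_rate_paln_pos_pct`,
#'   `ofr_rate_paln_neg_pct`, `paln_neg_share_of_ofr_pct`).
#' @export
contingency_summary <- function(records) {
  paln <- as.logical(records$paln)
  ofr <- as.logical(records$ofr_event)
  n_pos <- sum(paln)
  n_neg <- sum(!paln)
  n_ofr <- sum(ofr)
  list(n = length(paln), n_paln_pos = n_pos, n_ofr = n_ofr,
       ofr_in_paln_pos = sum(ofr & paln),
       ofr_in_paln_neg = sum(ofr & !paln),
       ofr_rate_paln_pos_pct = 100 * sum(ofr & paln) / n_pos,
       ofr_rate_paln_neg_pct = 100 * sum(ofr & !paln) / n_neg,
       paln_neg_share_of_ofr_pct = 100 * sum(ofr & !paln) / n_ofr)
}
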