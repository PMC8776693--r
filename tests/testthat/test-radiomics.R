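test_that("texture accumulators equal brute-force oracles on random volumes", {
  dirs <- lattice_directions(1)
  expect_equal(nrow(dirs), 13)
  withr::with_seed(42, {
    for (rep in 1:30) {
      d <- random_label_volume()
      ng <- attr(d, "n_levels")
      glcm <- build_glcm(d)
      expect_equal(unclass(glcm), oracle_glcm(unclass(d), ng, dirs),
                   ignore_attr = TRUE)
      got <- build_glrlm(d)
      want <- oracle_glrlm(unclass(d), ng, dirs)
      expect_equal(unclass(got)[, seq_len(ncol(want)), drop = FALSE], want,
                   ignore_attr = TRUE)
      gotz <- build_glszm(d)
      wantz <- oracle_glszm(unclass(d), ng)
      expect_equal(unclass(gotz)[, seq_len(ncol(wantz)), drop = FALSE], wantz,
                   ignore_attr = TRUE)
      nt <- build_ngtdm(d)
      ntw <- oracle_ngtdm(unclass(d), ng)
      expect_equal(nt$s, ntw$s)
      expect_equal(nt$n, ntw$n)
    }
  })
})

test_that("GLCM correlation behaves on striped, random and constant inputs", {
  # levels alternate along x, constant along y/z: directions orthogonal to
  # the variation see only (i, i) pairs -> per-direction correlation exactly 1
  stripes <- as_disc(array(rep(c(1L, 2L), length.out = 6)[
    rep(1:6, times = 36)], c(6, 6, 6)), 2)
  glcm <- build_glcm(stripes)
  dirs <- attr(glcm, "directions")
  along_y <- which(apply(dirs, 1, function(o) all(o == c(0, 1, 0))))
  expect_equal(oracle_glcm_correlation(glcm[, , along_y]), 1)
  along_x <- which(apply(dirs, 1, function(o) all(o == c(1, 0, 0))))
  expect_equal(oracle_glcm_correlation(glcm[, , along_x]), -1)

  # merged-matrix features equal the naive pair-count oracle
  withr::with_seed(7, d <- random_label_volume(max_dim = 4))
  ng <- attr(d, "n_levels")
  merged <- apply(build_glcm(d), c(1, 2), sum)
  omerged <- apply(oracle_glcm(unclass(d), ng, lattice_directions(1)),
                   c(1, 2), sum)
  expect_equal(glcm_features(build_glcm(d))[["GCorrelation1"]],
               oracle_glcm_correlation(omerged))

  # constant ROI -> correlation 0 by convention
  const <- as_disc(array(1L, c(4, 4, 4)), 3)
  expect_equal(glcm_features(build_glcm(const))[["GCorrelation1"]], 0)
})

test_that("run-length variance matches hand computation", {
  # single in-ROI row [1, 1, 2]: runs {(1, len 2), (2, len 1)} per the one
  # direction that traverses it; using a 3x1x1 volume all 13 directions see
  # the same row only along x
  row <- as_disc(array(c(1L, 1L, 2L), c(3, 1, 1)), 2)
  expect_s3_class(build_glrlm(row), "glrlm")
  # restricted to the x direction: runs {(1, len 2), (2, len 1)}
  runs <- oracle_glrlm(array(c(1L, 1L, 2L), c(3, 1, 1)), 2,
                       matrix(c(1L, 0L, 0L), 1))
  p <- runs / sum(runs)
  mu <- sum(p * col(p))
  expect_equal(sum(p * (col(p) - mu)^2), 0.25)

  # all-distinct labels -> every run has length 1 -> RLV = 0
  dist <- as_disc(array(1:8, c(2, 2, 2)), 8)
  expect_equal(glrlm_features(build_glrlm(dist))[["RLV"]], 0)
})

test_that("size-zone features reduce to single-term sums on one zone", {
  # one 26-connected zone of 4 voxels at level 1 (plus empty level 2)
  lab <- array(0L, c(4, 4, 4))
  lab[1:2, 1:2, 1] <- 1L
  d <- as_disc(lab, 2)
  f <- glszm_features(build_glszm(d))
  expect_equal(f[["LZE"]], 16)
  expect_equal(f[["LGZE"]], 1)
  expect_equal(f[["SZLGE"]], 1 / 16)
  expect_equal(f[["LZHGE"]], 16)
  expect_equal(f[["ZLV"]], 0)

  # all-distinct labels -> every zone size 1 -> LZE = 1, ZLV = 0
  dist <- as_disc(array(1:8, c(2, 2, 2)), 8)
  fd <- glszm_features(build_glszm(dist))
  expect_equal(fd[["LZE"]], 1)
  expect_equal(fd[["ZLV"]], 0)
})

test_that("NGTDM busyness matches the neighbourhood-loop oracle", {
  # two-level 3D checkerboard
  idx <- array(0L, c(3, 3, 3))
  for (i in 1:3) for (j in 1:3) for (k in 1:3)
    idx[i, j, k] <- 1L + (i + j + k) %% 2L
  d <- as_disc(idx, 2)
  nt <- build_ngtdm(d)
  ow <- oracle_ngtdm(idx, 2)
  expect_equal(nt$s, ow$s)
  p <- ow$n / sum(ow$n)
  busy_hand <- sum(p * ow$s) / sum(abs(outer(1:2 * p, 1:2 * p, "-")))
  expect_equal(ngtdm_features(nt)[["Busyness"]], busy_hand)
  # constant ROI -> busyness 0 by convention
  const <- as_disc(array(1L, c(3, 3, 3)), 2)
  expect_equal(ngtdm_features(build_ngtdm(const))[["Busyness"]], 0)
})

test_that("histogram features match closed forms", {
  f <- histogram_features(c(1, 2, 3))
  expect_equal(unname(f[c("Mean", "Variance", "Skewness", "Energy")]),
               c(2, 2 / 3, 0, 14))
  # unit exponential has skewness 2
  withr::with_seed(3, x <- rexp(1e5))
  expect_lt(abs(histogram_features(x)[["Skewness"]] - 2), 0.1)
  # constant input flags the skewness convention
  fc <- histogram_features(rep(2, 5))
  expect_equal(fc[["Skewness"]], 0)
  expect_true(attr(fc, "degenerate"))
})

test_that("shape features are exact on degenerate regions and spheres", {
  one <- array(FALSE, c(5, 5, 5)); one[3, 3, 3] <- TRUE
  f1 <- shape_features(roi_mask(one, c(2, 2, 2)))
  expect_equal(f1[["Volume_ml"]], 0.008)
  expect_equal(f1[["Max3Ddiameter"]], 0)

  two <- one; two[4, 4, 4] <- TRUE
  f2 <- shape_features(roi_mask(two, c(2, 2, 2)))
  expect_equal(f2[["Max3Ddiameter"]], sqrt(12))

  # rasterized ball at 1 mm: sphericity disproportion -> 1 within 5%
  sph <- make_sphere(20, 1)
  fs <- shape_features(roi_mask(sph, c(1, 1, 1)))
  expect_lt(abs(fs[["SpheDisproportion"]] - 1), 0.05)
  expect_lt(abs(fs[["Volume_ml"]] - 4 / 3 * pi * 8), 4 / 3 * pi * 8 * 0.05)
  expect_error(shape_features(roi_mask(array(FALSE, c(3, 3, 3)), c(1, 1, 1))),
               "empty")
})

test_that("the full extractor respects the registry and its naming scheme", {
  cfg <- cohort_config(n_patients = 1, image_shape = c(20L, 20L, 20L),
                       volume_range_ml = c(4, 6), seed = 31)
  co <- simulate_cohort(cfg)
  img <- co$images[[1]]; msk <- co$masks[[1]]

  # registry restricted to Mean only -> one feature per band
  slim <- feature_registry(histogram = "Mean", glcm = character(0),
                           glrlm = character(0), glszm = character(0),
                           ngtdm = character(0), shape = character(0))
  f <- extract_features(img, msk, registry = slim)
  expect_equal(names(f), paste0(band_codes(), "Mean"))

  # default registry covers every feature named in the published selections
  full <- extract_features(img, msk)
  published <- c("HHHRLV", "HHLSkewness", "HLHGCorrelation1", "HLHSZLGE",
                 "HLHSkewness", "HLLLGZE", "HLLGCorrelation", "LLHLZE",
                 "LLHMean", "ROIBusyness", "Max3Ddiameter", "LLLVariance",
                 "HHHZLV", "HLHLZLGE", "HLLGLV", "HLLGCorrelation1",
                 "LHHMean", "LHLRLV", "LLLRLV", "ROIEnergy", "ROILZHGE",
                 "SpheDisproportion")
  expect_length(published, 22)
  expect_true(all(published %in% names(full)))
  expect_length(full, length(registry_feature_names()))
  expect_true(all(is.finite(full)))

  # two runs on the same input are bit-identical
  expect_identical(full, extract_features(img, msk))
})

test_that("direction-pooled texture features are 90-degree rotation
          invariant", {
  rot_z <- function(a) {
    b <- aperm(a, c(2, 1, 3))
    b[dim(b)[1]:1, , , drop = FALSE]
  }
  withr::with_seed(77, {
    for (rep in 1:5) {
      d <- random_label_volume(max_dim = 5)
      ng <- attr(d, "n_levels")
      dr <- as_disc(rot_z(unclass(d)), ng)
      expect_equal(glcm_features(build_glcm(d)),
                   glcm_features(build_glcm(dr)))
      expect_equal(glrlm_features(build_glrlm(d)),
                   glrlm_features(build_glrlm(dr)))
      expect_equal(glszm_features(build_glszm(d)),
                   glszm_features(build_glszm(dr)))
      expect_equal(ngtdm_features(build_ngtdm(d)),
                   ngtdm_features(build_ngtdm(dr)))
    }
  })
})

test_that("affine intensity changes never reach the features", {
  cfg <- cohort_config(n_patients = 1, image_shape = c(16L, 16L, 16L),
                       volume_range_ml = c(3, 4), seed = 5)
  co <- simulate_cohort(cfg)
  img <- co$images[[1]]
  shifted <- image_volume(2.5 * img$values + 40, img$spacing_mm)
  for (norm in c("zscore", "minmax"))
    expect_equal(extract_features(img, co$masks[[1]], normalization = norm),
                 extract_features(shifted, co$masks[[1]],
                                  normalization = norm),
                 tolerance = 1e-9)
})
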