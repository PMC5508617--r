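test_that("the feature vocabulary has the documented family structure", {
  nm <- feature_names()
  expect_length(nm, 233L)
  expect_false(anyDuplicated(nm) > 0)
  fam <- table(feature_family(nm))
  expect_equal(unname(fam[c("IHF", "GLCM", "GLGCM", "GLRLM", "GWTF", "ISZM")]),
               c(3L, 80L, 15L, 44L, 80L, 11L), ignore_attr = TRUE)
  local <- sum(fam[c("IHF", "GLCM", "GLGCM", "GLRLM")])
  expect_equal(local, 142L)
})

test_that("histogram features: symmetry, closed forms, degenerate ROI", {
  # symmetric two-point distribution: zero skewness, excess kurtosis -2
  M <- matrix(rep(c(3, 7), 18), 6, 6)
  f <- ihf_features(roi_image(M, matrix(TRUE, 6, 6)))
  expect_equal(unname(f["IHF_Skewness"]), 0)
  expect_equal(unname(f["IHF_Kurtosis"]), -2)
  # variance is the unbiased estimator on the in-mask pixels only
  set.seed(30)
  M <- matrix(stats::rnorm(36, 10, 2), 6, 6)
  mask <- matrix(FALSE, 6, 6); mask[1:5, 1:4] <- TRUE
  f <- ihf_features(roi_image(M, mask))
  expect_equal(unname(f["IHF_Variance"]), stats::var(M[mask]))
  # large Gaussian sample: excess kurtosis near 0
  set.seed(31)
  M <- matrix(stats::rnorm(10000), 100, 100)
  f <- ihf_features(roi_image(M, matrix(TRUE, 100, 100)))
  expect_lt(abs(f[["IHF_Kurtosis"]]), 0.15)
  expect_warning(ihf_features(constant_roi(6)), "degenerate")
})

test_that("GLCM features: constant ROI limits and the two-level stripe", {
  qc <- quantize(constant_roi(8, 3), 32)
  for (d in c(1, 2, 4, 8)) {
    f <- glcm_features(lapply(c(0, 45, 90, 135),
                              function(th) build_glcm(qc, d, th)))
    expect_equal(unname(f[paste0("GLCM_Energy_mean_d", d)]), 1)
    expect_equal(unname(f[paste0("GLCM_Entropy_mean_d", d)]), 0)
    expect_equal(unname(f[paste0("GLCM_Contrast_mean_d", d)]), 0)
    expect_equal(unname(f[paste0("GLCM_Homogeneity_mean_d", d)]), 1)
  }
  # 1xN alternating stripe, d=1, 0 deg: Contrast 1, Energy 0.5
  q <- make_qroi(matrix(rep(c(1L, 2L), 10), 1, 20), 4L)
  f1 <- livertex:::glcm_features_single(build_glcm(q, 1, 0))
  expect_equal(unname(f1["Contrast"]), 1)
  expect_equal(unname(f1["Energy"]), 0.5)
})

test_that("matrix features equal their direct-summation oracles", {
  set.seed(37)
  for (rep in 1:6) {
    lev <- random_levels(10, 10, R = 6L)
    q <- make_qroi(lev, 16L)
    for (th in c(0, 90)) {
      g <- build_glcm(q, 1, th)
      got <- livertex:::glcm_features_single(g)
      expect_equal(unname(got), unname(oracle_glcm_features(g$matrix)),
                   tolerance = 1e-10)
      rl <- build_glrlm(q, th)
      got <- glrlm_features(rl)
      expect_equal(unname(got),
                   unname(oracle_glrlm_features(rl$matrix, rl$n_pixels)),
                   tolerance = 1e-10)
    }
    iz <- build_iszm(q, 8L)
    expect_equal(unname(iszm_features(iz)),
                 unname(oracle_iszm_features(iz$matrix, iz$n_pixels)),
                 tolerance = 1e-10)
  }
  set.seed(41)
  M <- matrix(stats::runif(144, 0, 30), 12, 12)
  roi <- roi_image(M, matrix(TRUE, 12, 12))
  gg <- build_glgcm(quantize(roi, 16), roi)
  expect_equal(unname(glgcm_features(gg)),
               unname(oracle_glgcm_features(gg$matrix)), tolerance = 1e-10)
})

test_that("GLGCM features: degenerate limits and ramp-vs-shuffle ordering", {
  roi <- constant_roi(8, 4)
  f <- glgcm_features(build_glgcm(quantize(roi, 16), roi))
  expect_equal(unname(f["GLGCM_GradientVariance"]), 0)
  expect_equal(unname(f["GLGCM_MixtureEntropy"]), 0)
  # shuffling a smooth ramp raises the Sobel gradient magnitudes the
  # matrix is built from (the gradient bins themselves are re-normalized
  # per image, so the comparison lives at the operator level)
  set.seed(43)
  for (k in 1:10) {
    M <- matrix(rep(seq(0, 44, by = 4), each = 12), 12, 12) +
      matrix(stats::rnorm(144), 12, 12)
    Ms <- matrix(sample(M), 12, 12)
    expect_lt(mean(livertex:::sobel_magnitude(M)),
              mean(livertex:::sobel_magnitude(Ms)))
  }
})

test_that("run-length features: all-distinct ROI and the hand-computed row", {
  lev <- matrix(sample(1:16), 4, 4)
  f <- glrlm_features(build_glrlm(make_qroi(lev, 16L), 0))
  expect_equal(unname(f["GLRLM_SRE_0deg"]), 1)
  expect_equal(unname(f["GLRLM_LRE_0deg"]), 1)
  expect_equal(unname(f["GLRLM_RunPercentage_0deg"]), 1)
  # row [1,1,1,2,2]: SRE = (1/9 + 1/4)/2 = 13/72
  f <- glrlm_features(build_glrlm(make_qroi(matrix(c(1L,1L,1L,2L,2L), 1, 5), 4L), 0))
  expect_equal(unname(f["GLRLM_SRE_0deg"]), 13 / 72)
})

test_that("size-zone features: zone percentage and low-intensity limits", {
  # single zone of 9 pixels: ZonePercentage 1/9
  f <- iszm_features(build_iszm(make_qroi(matrix(5L, 3, 3), 16L)))
  expect_equal(unname(f["ISZM_ZonePercentage"]), 1 / 9)
  # constant ROI quantizes to the lowest level: LowIntensityEmphasis 1
  f <- iszm_features(build_iszm(quantize(constant_roi(5, 99), 16)))
  expect_equal(unname(f["ISZM_LowIntensityEmphasis"]), 1)
})

test_that("extract_all returns 233 finite features, even for flat ROIs", {
  sp <- phantom_spec(image_size = c(96L, 96L), roi_radius_range = c(8, 12))
  f <- extract_all(generate_phantom(sp, "classC", seed = 9))
  expect_identical(names(f), feature_names())
  expect_true(all(is.finite(f)))
  f0 <- extract_all(constant_roi(24, 50))
  expect_length(f0, 233L)
  expect_true(all(is.finite(f0)))
})

test_that("features ignore out-of-mask pixels entirely", {
  sp <- phantom_spec(image_size = c(96L, 96L), roi_radius_range = c(9, 12))
  roi <- generate_phantom(sp, "classB", seed = 77)
  f1 <- extract_all(roi)
  roi2 <- roi
  set.seed(1)
  roi2$pixels[!roi2$mask] <- stats::runif(sum(!roi2$mask), 0, 1e4)
  f2 <- extract_all(roi2)
  # the Wiener filter runs on the whole slice, so compare with it disabled
  cfg <- default_config(); cfg$wiener$enabled <- FALSE
  expect_equal(extract_all(roi2, cfg), extract_all(roi, cfg),
               tolerance = 1e-10)
})

test_that("regional size-zone statistics are the discretization-sensitive ones", {
  sp <- phantom_spec(image_size = c(96L, 96L), roi_radius_range = c(9, 14),
                     seed = 6L)
  rois <- lapply(1:20, function(s)
    generate_phantom(sp, c("classB", "classC")[(s %% 2) + 1], seed = 200 + s))
  sens <- discretization_sensitivity(rois, c(16L, 128L))
  expect_true(all(c("local", "iszm_regional") %in% names(sens)))
  tt <- stats::t.test(sens$iszm_regional, sens$local, paired = TRUE,
                      alternative = "greater")
  expect_gt(mean(sens$iszm_regional), mean(sens$local))
  expect_lt(tt$p.value, 0.05)
})
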