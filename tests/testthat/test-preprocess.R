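# Preprocessing chain: common axis, resampling, mean spectra, peak picking,
# alignment-peak selection, per-pixel alignment, calibration, feature
# extraction and robust TIC normalization.

test_that("geometric axis has constant ppm spacing and the expected size", {
  ax <- build_common_axis(300, 300)
  expect_identical(length(ax$edges), 1L)
  ax <- build_common_axis(300, 2000, 1.5)
  ratios <- ax$edges[-1] / ax$edges[-length(ax$edges)]
  expect_lt(max(abs(ratios - (1 + 1.5e-6))), 1e-12)
  # oracle: bin count from the closed-form logarithm ratio
  expected <- log(2000 / 300) / (1.5e-6)
  expect_lte(abs(length(ax$edges) - expected), 3)
  expect_gte(ax$edges[length(ax$edges)], 2000)
  expect_error(build_common_axis(300, 2000, 0), "positive")
})

test_that("resampling conserves in-range intensity exactly", {
  ax <- build_common_axis(400, 500, 10)
  v <- resample_spectrum(numeric(), numeric(), ax)
  expect_true(all(v == 0))
  mz <- c(401.5, 433.2, 433.2004, 499.9, 600)  # last is out of range
  int <- c(5, 2, 3, 1, 7)
  v <- resample_spectrum(mz, int, ax)
  expect_identical(sum(v), sum(int[1:4]))
  expect_identical(attr(v, "n_dropped"), 1L)
  # two centroids ~0.9 ppm apart fall in one 10 ppm bin and are summed
  j <- sddmark:::axis_bin(433.2, ax)
  expect_identical(v[j], 5)
})

test_that("mean spectrum averages pixels and rejects mixed polarity", {
  ax <- build_common_axis(400, 500, 10)
  one <- toy_dataset(list(cbind(c(420, 450), c(2, 4))), mz_range = c(400, 500))
  expect_identical(mean_spectrum(one, ax),
                   as.numeric(resample_spectrum(c(420, 450), c(2, 4), ax)))
  two <- toy_dataset(list(cbind(c(420, 450), c(2, 4)),
                          cbind(c(420, 450), c(2, 4))), mz_range = c(400, 500))
  expect_identical(mean_spectrum(two, ax), mean_spectrum(one, ax))
  neg <- toy_dataset(list(cbind(420, 1)), polarity = "negative",
                     mz_range = c(400, 500))
  expect_error(mean_spectrum(list(one, neg), ax), "polarity")
})

test_that("peak picking recovers planted peaks and retains isotopes", {
  ax <- build_common_axis(400, 600, 1.5)
  expect_identical(length(pick_peaks(rep(0, length(ax$edges) - 1L), ax)), 0L)
  planted <- c(420.123, 455.5, 500.0021, 533.3, 580.9)
  spec <- resample_spectrum(planted, rep(100, 5), ax)
  got <- pick_peaks(spec, ax)
  expect_identical(length(got), 5L)
  expect_ppm_equal(as.numeric(got), planted, tol_ppm = 1)
  # an isotope pair 1.003355 apart is kept as two features
  pair <- c(500.0, 501.003355)
  got2 <- pick_peaks(resample_spectrum(pair, c(100, 30), ax), ax)
  expect_identical(length(got2), 2L)
  expect_ppm_equal(as.numeric(got2), pair, tol_ppm = 1)
})

test_that("noiseless phantom mean spectrum yields exactly the planted peaks", {
  ph <- generate_phantom(clean_phantom_config())
  ax <- build_common_axis(300, 2000, 1.5)
  avg <- mean_spectrum(ph$dataset, ax)
  got <- pick_peaks(avg, ax)
  expect_identical(length(got), length(unique(round(ph$truth$panel_mz, 6))))
  expect_ppm_equal(as.numeric(got), sort(ph$truth$panel_mz), tol_ppm = 1)
})

test_that("alignment-peak selection honours occupancy and count", {
  # 8 species at well-spaced m/z, present in controlled fractions of pixels
  mzs <- seq(400, 1100, by = 100)
  occs <- c(1, .9, .8, .7, .6, .55, .4, .3)
  n <- 200
  peaks <- lapply(seq_len(n), function(i) {
    keep <- occs >= (i - 0.5) / n
    cbind(mzs[keep], rep(50, sum(keep)))
  })
  ds <- toy_dataset(peaks)
  am <- select_alignment_peaks(ds, n_peaks = 6, min_fraction = 0.5)
  expect_identical(length(am$reference_peaks), 6L)
  expect_ppm_equal(sort(am$reference_peaks), mzs[occs >= 0.5], tol_ppm = 2)
  expect_true(all(am$occupancy >= 0.5))
  expect_error(select_alignment_peaks(ds, n_peaks = 7, min_fraction = 0.5),
               "only 6")
})

test_that("per-pixel scalar alignment recovers known shifts", {
  refs <- c(450, 550, 650, 750, 850, 950)
  # oracle: dense grid search over candidate shifts maximizing closeness
  grid_oracle <- function(mz, refs) {
    cand <- seq(-20, 20, by = 0.05)
    cost <- vapply(cand, function(s) {
      shifted <- refs * (1 + s * 1e-6)
      sum(vapply(shifted, function(r) min(abs(mz - r) / r * 1e6), numeric(1)))
    }, numeric(1))
    cand[which.min(cost)]
  }
  mz0 <- refs                                   # no drift
  expect_lt(abs(align_pixel_shift(mz0, refs)), 0.5)
  mz10 <- refs * (1 + 10e-6)                    # uniform +10 ppm
  est <- align_pixel_shift(mz10, refs)
  expect_lt(abs(est - 10), 1)
  expect_lt(abs(est - grid_oracle(mz10, refs)), 0.5)
  # only 3 of 6 references present
  mz3 <- refs[c(1, 3, 5)] * (1 + 10e-6)
  expect_lt(abs(align_pixel_shift(mz3, refs) - 10), 1)
  # fewer than 2 matches: NA from the estimator, warning + zero from the
  # dataset-level wrapper
  expect_true(is.na(align_pixel_shift(refs[1] * (1 + 5e-6), refs)))
  ds <- toy_dataset(list(cbind(refs, 10), cbind(refs[1], 10)),
                    mz_range = c(400, 1000))
  expect_warning(out <- align_dataset(ds, refs), "unaligned")
  expect_identical(out$shift_ppm[2], 0)
  expect_identical(out$dataset$mz[[2]], ds$mz[[2]])
})

test_that("ambiguous references are excluded from the shift estimate", {
  refs <- c(450, 550, 650, 750, 850, 950)
  # two centroids flank the first reference inside the search window
  mz <- sort(c(450 * (1 - 8e-6), 450 * (1 + 6e-6), refs[-1] * (1 + 10e-6)))
  est <- align_pixel_shift(mz, refs, max_shift_ppm = 25)
  expect_lt(abs(est - 10), 0.5)
})

test_that("calibration recovers a known linear ppm error model", {
  cals <- calibrant_table()$theoretical_mz
  species <- sort(c(cals, seq(420, 1800, by = 85)))
  a <- 4; b <- -0.002
  n <- 40
  peaks <- lapply(seq_len(n), function(i) {
    err <- (a + b * species) * 1e-6
    cbind(species * (1 + err), rep(100, length(species)))
  })
  ds <- toy_dataset(peaks)
  # a 0.1 ppm axis keeps bin quantization well below the tolerances probed
  fine <- build_common_axis(600, 950, 0.1)
  out <- calibrate(ds, cals, axis = fine)
  # oracle: closed-form least squares on the two-parameter model is exact
  # here, so the coefficients must match the planted (a, b)
  expect_lt(abs(unname(out$model$coefficients[1]) - a), 0.2)
  expect_lt(abs(unname(out$model$coefficients[2]) - b), 3e-4)
  expect_lt(max(abs(out$model$residual_ppm)), 0.1)
  # corrected spectra sit at the true positions (linear model is global)
  expect_ppm_equal(out$dataset$mz[[1]], species, tol_ppm = 0.3)
  # zero-error input: identity correction
  clean <- toy_dataset(lapply(1:10, function(i) cbind(species, 100)))
  out0 <- calibrate(clean, cals, axis = fine)
  expect_lt(max(abs(out0$model$residual_ppm)), 0.1)
  expect_ppm_equal(out0$dataset$mz[[1]], species, tol_ppm = 0.2)
  # too few matched calibrants
  expect_error(calibrate(ds, cals[1:3], axis = fine), "4")
})

test_that("feature extraction assigns centroids to clipped ppm windows", {
  feats <- c(500, 500.01, 600)   # first two are 20 ppm apart
  ds <- toy_dataset(list(cbind(c(500.000), 10),
                         cbind(c(500.004), 7),    # 8 ppm from f1, 12 from f2
                         cbind(c(450), 5)),       # near nothing
                    mz_range = c(400, 700))
  fm <- extract_features(ds, feats, tol_ppm = 7)
  expect_identical(fm$values[1, ], c(10, 0, 0))
  expect_identical(fm$values[2, ], c(0, 0, 0))    # beyond 7 ppm of either
  expect_identical(fm$values[3, ], c(0, 0, 0))
  # midpoint clipping: a centroid 6 ppm above f1 is within 7 ppm of f1 but
  # closer to f1 than f2, so it lands in f1
  ds2 <- toy_dataset(list(cbind(500 * (1 + 6e-6), 4)), mz_range = c(400, 700))
  fm2 <- extract_features(ds2, feats, tol_ppm = 7)
  expect_identical(fm2$values[1, ], c(4, 0, 0))
  expect_error(extract_features(ds, c(500, 500), 7), "duplicate")
})

test_that("deposit-exclusive feature columns vanish outside the mask", {
  ph <- generate_phantom(clean_phantom_config())
  fm <- extract_features(ph$dataset, sort(ph$truth$panel_mz), tol_ppm = 7)
  outside <- !ph$truth$deposit_mask[cbind(fm$pixel_index[, 2] + 1L,
                                          fm$pixel_index[, 1] + 1L)]
  for (m in ph$truth$true_marker_mz) {
    j <- which.min(abs(fm$feature_mz - m))
    expect_true(all(fm$values[outside, j] == 0))
  }
})

test_that("robust TIC normalization matches its closed-form behaviour", {
  base <- c(5, 8, 12, 20, 33, 50, 80, 120, 200, 400)
  ds <- toy_dataset(list(cbind(seq(500, 590, by = 10), base),
                         cbind(seq(500, 590, by = 10), 2 * base),
                         cbind(seq(500, 590, by = 10), base)),
                    mz_range = c(400, 700))
  fm <- extract_features(ds, seq(500, 590, by = 10), tol_ppm = 7)
  nm <- robust_tic_normalize(fm)
  # identical pixels share a factor; a doubled pixel gets half the factor
  expect_identical(nm$norm_factors[1], nm$norm_factors[3])
  expect_equal(nm$norm_factors[2], nm$norm_factors[1] / 2, tolerance = 1e-12)
  expect_equal(nm$values[1, ], nm$values[2, ], tolerance = 1e-12)
  # idempotence: factors on a second pass are 1
  nm2 <- robust_tic_normalize(nm)
  expect_equal(nm2$norm_factors, rep(1, 3), tolerance = 1e-9)
})

test_that("a single huge spike barely changes a pixel's robust TIC", {
  # realistic per-pixel peak counts (real pixels carry 1e4-1e5 centroids)
  with_seed(7, v <- stats::rlnorm(5000, log(50), 1))
  tic <- function(x) sddmark:::robust_tic(x, 0.05, 0.95)
  spiked <- c(v, 100 * max(v))
  expect_lt(abs(tic(spiked) / tic(v) - 1), 0.05)
})

test_that("all-zero pixels normalize with factor 1 and a warning", {
  ds <- toy_dataset(list(cbind(c(500, 510), c(5, 7)), cbind(c(500, 510), c(0, 0))),
                    mz_range = c(400, 700))
  expect_warning(nm <- robust_tic_normalize(ds), "all-zero")
  expect_identical(attr(nm, "norm_factors")[2], 1)
})

test_that("alignment plus calibration reaches sub-ppm accuracy on a drifting phantom", {
  cfg <- small_phantom_config(seed = 9, drift_ppm_range = 15,
                              global_error_ppm = c(3, 0.002))
  ph <- generate_phantom(cfg)
  pp <- suppressWarnings(preprocess_dataset(ph$dataset,
                                            calibrant_table()$theoretical_mz))
  expect_lte(pp$calibration$median_abs_residual_ppm, 1)
  expect_identical(pp$matrix$normalized, TRUE)
  expect_identical(nrow(pp$matrix$values), length(ph$dataset))
})
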