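# TreeSHAP interpretation: additivity, the brute-force Shapley oracle,
# global ranking with direction, SHAP maps and the marker shortlist.

interp_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ph <- generate_phantom(small_phantom_config(seed = 6))
      fm <- extract_features(ph$dataset, sort(ph$truth$panel_mz), tol_ppm = 20)
      fm <- suppressWarnings(robust_tic_normalize(fm))
      mask <- new_label_mask(ifelse(ph$truth$deposit_mask, "SDD", "background"))
      tl <- balance_labels(mask, seed = 6)
      model <- sdd_classifier(fm, tl, nrounds = 100, seed = 6)
      shap <- shap_values(model, fm)
      cache <<- list(ph = ph, fm = fm, model = model, shap = shap)
    }
    cache
  }
})

test_that("SHAP additivity holds at every pixel", {
  fx <- interp_fixture()
  margin <- predict(fx$model, fx$fm, type = "margin")
  recon <- fx$shap$base_value + rowSums(fx$shap$local_values)
  expect_lt(max(abs(recon - margin)), 1e-4)
})

test_that("features never split on receive zero SHAP everywhere", {
  fx <- interp_fixture()
  imp <- xgboost::xgb.importance(model = fx$model$booster)
  used <- as.integer(sub("f", "", imp$Feature)) + 1L
  unused <- setdiff(seq_along(fx$fm$feature_mz), used)
  expect_gt(length(unused), 0)
  expect_true(all(fx$shap$local_values[, unused] == 0))
  expect_true(all(fx$shap$direction[unused] == "none"))
})

test_that("TreeSHAP matches brute-force Shapley enumeration on small trees", {
  with_seed(8, {
    x <- matrix(stats::runif(400 * 6), ncol = 6)
    y <- as.integer(x[, 1] + 0.5 * x[, 3] + 0.1 * stats::runif(400) > 0.8)
  })
  for (depth in c(1L, 2L)) {
    dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
    booster <- xgboost::xgb.train(params = list(objective = "binary:logistic",
                                                max_depth = depth, eta = 1,
                                                nthread = 1),
                                  data = dtrain, nrounds = 1, verbose = 0)
    contrib <- predict(booster, xgboost::xgb.DMatrix(x[1:8, , drop = FALSE],
                                                     nthread = 1),
                       predcontrib = TRUE)
    for (i in 1:8) {
      bf <- brute_force_shapley(booster, x[i, ])
      expect_equal(unname(contrib[i, 1:6]), bf$phi, tolerance = 1e-5,
                   label = sprintf("depth %d pixel %d", depth, i))
    }
    # the model intercept is the same constant offset for base and margin
    margin <- predict(booster, xgboost::xgb.DMatrix(x[1:8, , drop = FALSE],
                                                    nthread = 1),
                      outputmargin = TRUE)
    bf <- brute_force_shapley(booster, x[1, ])
    leaf_total <- sum(bf$phi) + bf$base_value
    expect_equal(margin[1] - contrib[1, 7],
                 leaf_total - bf$base_value, tolerance = 1e-5)
  }
})

test_that("global ranking sorts by mean absolute SHAP with m/z tie-break", {
  fx <- interp_fixture()
  r <- global_ranking(fx$shap)
  expect_identical(nrow(r), length(fx$fm$feature_mz))
  expect_true(all(diff(r$global_score) <= 0))
  zero <- r[r$global_score == 0, ]
  expect_true(all(zero$direction == "none"))
  expect_true(all(diff(zero$feature_mz) > 0))   # ties ordered by m/z
  expect_setequal(r$feature_mz, fx$fm$feature_mz)
})

test_that("planted markers outrank everything and carry positive direction", {
  fx <- interp_fixture()
  r <- global_ranking(fx$shap)
  marker_rows <- vapply(fx$ph$truth$true_marker_mz, function(m)
    which.min(abs(r$feature_mz - m)), integer(1))
  expect_lte(max(r$rank[marker_rows]), 20)
  expect_true(all(r$direction[marker_rows] == "positive"))
})

test_that("SHAP maps render local values spatially", {
  fx <- interp_fixture()
  m <- fx$ph$truth$true_marker_mz[2]
  img <- shap_map(fx$shap, m)
  expect_identical(dim(img), dim(fx$ph$truth$deposit_mask))
  # ion image and SHAP map of an exclusive positive marker are correlated
  ion <- export_ion_image(fx$fm, m)
  ok <- !is.na(img)
  expect_gte(stats::cor(ion[ok], img[ok]), 0.8)
  # unknown feature errors; zero-SHAP feature gives an all-zero map
  expect_error(shap_map(fx$shap, 1999), "no feature")
  imp <- xgboost::xgb.importance(model = fx$model$booster)
  used <- as.integer(sub("f", "", imp$Feature)) + 1L
  j <- setdiff(seq_along(fx$fm$feature_mz), used)[1]
  img0 <- shap_map(fx$shap, fx$fm$feature_mz[j])
  expect_true(all(img0[!is.na(img0)] == 0))
  p <- file.path(tempdir(), "shapmap.png")
  shap_map(fx$shap, m, path = p)
  expect_true(file.exists(p))
  file.remove(p)
})

test_that("the shortlist joins annotations and cross-references isotopes", {
  fx <- interp_fixture()
  species <- expand_species_table(build_default_panel(n_filler_per_stratum = 6L))
  ann <- annotate_peaks(fx$fm$feature_mz, species, tol_ppm = 10)
  expect_identical(nrow(marker_shortlist(fx$shap, ann, top_n = 0)), 0L)
  sl <- marker_shortlist(fx$shap, ann, top_n = 20)
  expect_identical(nrow(sl), 20L)
  expect_identical(sl$rank, 1:20)
  # the LPC marker appears as monoisotopic + isotope pair, cross-referenced
  lpc_mono <- sl[grepl("^LPC\\(18:3\\)$", sl$annotation), ]
  lpc_iso <- sl[grepl("LPC\\(18:3\\) \\[13C x1\\]", sl$annotation), ]
  expect_gte(nrow(lpc_mono), 1)
  expect_gte(nrow(lpc_iso), 1)
  expect_identical(lpc_iso$isotope_of[1], "LPC(18:3)")
})

test_that("ranking and shortlist are stable across recomputation", {
  fx <- interp_fixture()
  again <- shap_values(fx$model, fx$fm)
  expect_identical(global_ranking(again), global_ranking(fx$shap))
})
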