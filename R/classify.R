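# Per-pixel SDD vs background classification with gradient-boosted trees.
# `sdd_classifier()` is the package's central fitting function: it splits the
# balanced labels 67/33 (stratified), trains an XGBoost model single-threaded
# for reproducibility, and evaluates held-out balanced accuracy, precision,
# recall and F1.

# Rows of the feature matrix corresponding to 0-based pixel coordinates.
match_pixels <- function(matrix, coords) {
  key <- matrix$pixel_index[, 1] + matrix$grid_shape[1] * matrix$pixel_index[, 2]
  want <- coords[, 1] + matrix$grid_shape[1] * coords[, 2]
  idx <- match(want, key)
  if (anyNA(idx)) stop_sddmark("labelled pixel(s) missing from the feature matrix")
  idx
}

#' Stratified train/test split of balanced labels
#'
#' Random split preserving the class balance: `train_fraction` of each class
#' goes to training, the rest to the held-out test set; disjoint by
#' construction and deterministic given the seed.
#'
#' @param labels A [balance_labels()] result.
#' @param train_fraction Fraction of each class used for training
#'   (default 0.67).
#' @param seed Integer seed.
#' @return list with `train` and `test`, each a list of `positive` and
#'   `negative` coordinate matrices.
#' @export
split_train_test <- function(labels, train_fraction = 0.67, seed = 1) {
  stopifnot(inherits(labels, "training_labels"),
            train_fraction > 0, train_fraction < 1)
  if (nrow(labels$positive) < 2 || nrow(labels$negative) < 2)
    stop_sddmark("need at least 2 pixels per class to split")
  with_seed(child_seed(seed, "split"), {
    take <- function(coords) {
      n <- nrow(coords)
      n_train <- round(n * train_fraction)
      idx <- sample.int(n, n_train)
      list(train = coords[idx, , drop = FALSE],
           test = coords[-idx, , drop = FALSE])
    }
    p <- take(labels$positive)
    n <- take(labels$negative)
  })
  list(train = list(positive = p$train, negative = n$train),
       test = list(positive = p$test, negative = n$test))
}

# Assemble an xgboost DMatrix-ready design from a split side.
side_design <- function(matrix, side) {
  rows <- c(match_pixels(matrix, side$positive), match_pixels(matrix, side$negative))
  y <- c(rep(1, nrow(side$positive)), rep(0, nrow(side$negative)))
  list(x = matrix$values[rows, , drop = FALSE], y = y, rows = rows)
}

#' Fit the SDD pixel classifier
#'
#' Trains a gradient-boosted decision-tree ensemble (XGBoost, logistic
#' objective) to classify pixels as SDD versus background from their feature
#' intensities, using a stratified 67/33 train/test split of the balanced
#' labels, and evaluates it on the held-out pixels. Training is
#' single-threaded so that a fixed seed reproduces the model exactly.
#'
#' @param matrix A normalized `feature_matrix`.
#' @param labels A [balance_labels()] result.
#' @param train_fraction Training fraction of the stratified split
#'   (default 0.67).
#' @param nrounds Number of boosting rounds (default 200).
#' @param max_depth Maximum tree depth (default 4).
#' @param eta Learning rate (default 0.1).
#' @param colsample_bytree Column subsample per tree (default 0.5; spreads
#'   importance across correlated isotopologue features, stabilizing the
#'   SHAP ranking).
#' @param seed Integer seed controlling split and training.
#' @param ... Additional parameters passed to [xgboost::xgb.train()].
#' @return Object of class `sdd_model`: the fitted booster, `feature_mz`
#'   (order-locked to the matrix), hyperparameters, the split, held-out
#'   `metrics`, and the seed.
#' @export
sdd_classifier <- function(matrix, labels, train_fraction = 0.67,
                           nrounds = 200, max_depth = 4, eta = 0.1,
                           colsample_bytree = 0.5, seed = 1, ...) {
  stopifnot(inherits(matrix, "feature_matrix"))
  if (!matrix$normalized)
    warning("feature matrix is not normalized; consider robust_tic_normalize()",
            call. = FALSE)
  split <- split_train_test(labels, train_fraction = train_fraction, seed = seed)
  tr <- side_design(matrix, split$train)
  if (length(unique(tr$y)) < 2) stop_sddmark("training set is single-class")
  params <- list(objective = "binary:logistic", max_depth = max_depth,
                 eta = eta, colsample_bytree = colsample_bytree,
                 nthread = 1, ...)
  booster <- with_seed(child_seed(seed, "xgb"), {
    dtrain <- xgboost::xgb.DMatrix(tr$x, label = tr$y, nthread = 1)
    xgboost::xgb.train(params = params, data = dtrain, nrounds = nrounds,
                       verbose = 0)
  })
  model <- structure(list(booster = booster, feature_mz = matrix$feature_mz,
                          hyperparameters = c(params, nrounds = nrounds,
                                              train_fraction = train_fraction),
                          split = split, seed = seed,
                          grid_shape = matrix$grid_shape),
                     class = "sdd_model")
  model$metrics <- evaluate_classifier(model, matrix, split$test)
  model
}

#' Held-out classification metrics
#'
#' Balanced accuracy (mean of per-class recalls) plus precision, recall and
#' F1 of the SDD class, at a 0.5 probability threshold.
#'
#' @param model An `sdd_model`.
#' @param matrix The `feature_matrix` the model was fitted on.
#' @param test A split side (list of `positive`/`negative` coordinate
#'   matrices); defaults to the model's held-out test set.
#' @param threshold Decision threshold on the SDD probability (default 0.5).
#' @return Object of class `sdd_metrics`: balanced_accuracy, precision,
#'   recall, f1, and the confusion counts.
#' @export
evaluate_classifier <- function(model, matrix, test = model$split$test,
                                threshold = 0.5) {
  te <- side_design(matrix, test)
  if (!length(te$y)) stop_sddmark("empty test set")
  train_rows <- c(match_pixels(matrix, model$split$train$positive),
                  match_pixels(matrix, model$split$train$negative))
  if (length(intersect(te$rows, train_rows)) && !identical(test, model$split$train))
    stop_sddmark("test pixels overlap the training set")
  prob <- predict(model$booster, xgboost::xgb.DMatrix(te$x, nthread = 1))
  pred <- as.integer(prob >= threshold)
  tp <- sum(pred == 1 & te$y == 1); fp <- sum(pred == 1 & te$y == 0)
  fn <- sum(pred == 0 & te$y == 1); tn <- sum(pred == 0 & te$y == 0)
  classification_metrics(tp = tp, fp = fp, fn = fn, tn = tn)
}

#' @rdname evaluate_classifier
#' @param tp,fp,fn,tn Confusion-matrix counts (SDD = positive class).
#' @export
classification_metrics <- function(tp, fp, fn, tn) {
  recall_pos <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  recall_neg <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall_pos) && precision + recall_pos > 0)
    2 * precision * recall_pos / (precision + recall_pos) else NA_real_
  structure(list(balanced_accuracy = mean(c(recall_pos, recall_neg)),
                 precision = precision, recall = recall_pos, f1 = f1,
                 confusion = c(tp = tp, fp = fp, fn = fn, tn = tn)),
            class = "sdd_metrics")
}

#' @export
print.sdd_metrics <- function(x, ...) {
  cat(sprintf("balanced accuracy %.4f | precision %.4f | recall %.4f | F1 %.4f\n",
              x$balanced_accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}

#' @export
print.sdd_model <- function(x, ...) {
  hp <- x$hyperparameters
  cat(sprintf("<sdd_model> XGBoost, %d rounds, depth %d, eta %g, %d features\n",
              hp$nrounds, hp$max_depth, hp$eta, length(x$feature_mz)))
  cat(sprintf("  train %d / test %d pixels (stratified %.0f/%.0f split)\n",
              nrow(x$split$train$positive) + nrow(x$split$train$negative),
              nrow(x$split$test$positive) + nrow(x$split$test$negative),
              100 * hp$train_fraction, 100 * (1 - hp$train_fraction)))
  cat("  held-out: "); print(x$metrics)
  invisible(x)
}

#' @export
summary.sdd_model <- function(object, ...) {
  print(object)
  imp <- xgboost::xgb.importance(model = object$booster)
  cat("\nTop features by gain:\n")
  print(utils::head(as.data.frame(imp), 10))
  invisible(object)
}

#' Predict SDD probabilities
#'
#' @param object An `sdd_model`.
#' @param matrix A `feature_matrix` with the same feature set.
#' @param type `"prob"` for a per-pixel probability vector, `"map"` for a
#'   `grid_height x grid_width` probability image (pixels absent from the
#'   matrix are `NA`), `"margin"` for raw log-odds.
#' @param ... Unused.
#' @return Numeric vector or matrix of predictions.
#' @export
predict.sdd_model <- function(object, matrix, type = c("prob", "map", "margin"),
                              ...) {
  type <- match.arg(type)
  stopifnot(inherits(matrix, "feature_matrix"))
  if (!identical(length(matrix$feature_mz), length(object$feature_mz)) ||
      max(abs(matrix$feature_mz - object$feature_mz)) > 1e-9)
    stop_sddmark("feature m/z values do not match the fitted model")
  dm <- xgboost::xgb.DMatrix(matrix$values, nthread = 1)
  prob <- predict(object$booster, dm, outputmargin = (type == "margin"))
  if (type != "map") return(prob)
  img <- matrix(NA_real_, nrow = matrix$grid_shape[2], ncol = matrix$grid_shape[1])
  img[cbind(matrix$pixel_index[, 2] + 1L, matrix$pixel_index[, 1] + 1L)] <- prob
  img
}

#' @export
plot.sdd_model <- function(x, matrix, ...) {
  img <- predict(x, matrix, type = "map")
  graphics::image(t(img)[, rev(seq_len(nrow(img)))], axes = FALSE,
                  col = grDevices::hcl.colors(64, "viridis"),
                  main = "SDD probability map", ...)
  invisible(img)
}
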