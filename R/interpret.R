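# Model interpretation: exact TreeSHAP local importance values per pixel and
# feature, global ranking with direction (red = intensity increase raises the
# SDD probability, blue = lowers it), spatial SHAP maps, and the top-N marker
# shortlist with lipid annotation and isotope cross-referencing.

#' Per-pixel SHAP values for an SDD classifier
#'
#' Exact tree-path Shapley values (TreeSHAP) of the fitted gradient-boosted
#' model, in log-odds units, for every pixel of the matrix. The additivity
#' identity `base_value + sum(local values) = model margin` holds at every
#' pixel.
#'
#' @param model An `sdd_model`.
#' @param matrix A `feature_matrix` with the model's feature set.
#' @return Object of class `sdd_shap`: `local_values` (pixels x features),
#'   `base_value`, per-feature `global_score` (mean |local value|),
#'   `direction` (`"positive"`, `"negative"` or `"none"`), `ranking`
#'   (feature order, decreasing score, ties to lower m/z), `feature_mz`.
#' @export
shap_values <- function(model, matrix) {
  stopifnot(inherits(model, "sdd_model"), inherits(matrix, "feature_matrix"))
  if (max(abs(matrix$feature_mz - model$feature_mz)) > 1e-9)
    stop_sddmark("feature m/z values do not match the fitted model")
  dm <- xgboost::xgb.DMatrix(matrix$values, nthread = 1)
  contrib <- predict(model$booster, dm, predcontrib = TRUE)
  m <- length(model$feature_mz)
  local <- contrib[, seq_len(m), drop = FALSE]
  base <- contrib[1, m + 1L]
  global <- colMeans(abs(local))
  dir <- vapply(seq_len(m), function(j) {
    lv <- local[, j]
    if (all(lv == 0)) return("none")
    x <- matrix$values[, j]
    if (stats::sd(x) == 0 || stats::sd(lv) == 0) return("none")
    if (stats::cor(x, lv) >= 0) "positive" else "negative"
  }, character(1))
  ranking <- order(-global, matrix$feature_mz)
  structure(list(local_values = local, base_value = base,
                 global_score = global, direction = dir, ranking = ranking,
                 feature_mz = matrix$feature_mz,
                 pixel_index = matrix$pixel_index,
                 grid_shape = matrix$grid_shape),
            class = "sdd_shap")
}

#' @export
print.sdd_shap <- function(x, ...) {
  cat(sprintf("<sdd_shap> %d pixels x %d features, base value %.4f\n",
              nrow(x$local_values), ncol(x$local_values), x$base_value))
  top <- x$ranking[seq_len(min(5, length(x$ranking)))]
  cat("  top features: ",
      paste(sprintf("m/z %.4f (%s)", x$feature_mz[top], x$direction[top]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Global SHAP ranking table
#'
#' @param shap An [shap_values()] result.
#' @return data.frame, one row per feature in decreasing global-importance
#'   order: rank, feature_mz, global_score, direction.
#' @export
global_ranking <- function(shap) {
  stopifnot(inherits(shap, "sdd_shap"))
  idx <- shap$ranking
  data.frame(rank = seq_along(idx), feature_mz = shap$feature_mz[idx],
             global_score = shap$global_score[idx],
             direction = shap$direction[idx], stringsAsFactors = FALSE)
}

#' Spatial SHAP map of one feature
#'
#' The feature's local SHAP values rendered on the pixel grid. Positive
#' values (raising the SDD probability) map to red, negative to blue, zero to
#' white, on a symmetric diverging scale.
#'
#' @param shap An [shap_values()] result.
#' @param feature_mz The feature's m/z (nearest within `tol_ppm`).
#' @param path Optional PNG output path (diverging red-white-blue rendering).
#' @param tol_ppm Feature matching tolerance (default 7 ppm).
#' @return Invisibly, the SHAP map as a `grid_height x grid_width` matrix
#'   (NA where no pixel was measured).
#' @export
shap_map <- function(shap, feature_mz, path = NULL, tol_ppm = 7) {
  stopifnot(inherits(shap, "sdd_shap"))
  err <- abs(ppm_error(feature_mz, shap$feature_mz))
  j <- which.min(err)
  if (err[j] > tol_ppm)
    stop_sddmark("no feature within %.1f ppm of m/z %.4f", tol_ppm, feature_mz)
  img <- matrix(NA_real_, nrow = shap$grid_shape[2], ncol = shap$grid_shape[1])
  img[cbind(shap$pixel_index[, 2] + 1L, shap$pixel_index[, 1] + 1L)] <-
    shap$local_values[, j]
  if (!is.null(path)) {
    mx <- max(abs(img), na.rm = TRUE)
    v <- img / if (mx > 0) mx else 1          # [-1, 1], NA -> white
    v[is.na(v)] <- 0
    rgb_arr <- array(1, dim = c(nrow(img), ncol(img), 3))
    rgb_arr[, , 2] <- 1 - abs(v)              # green fades with |value|
    rgb_arr[, , 3] <- 1 - pmax(v, 0)          # blue removed where positive
    rgb_arr[, , 1] <- 1 - pmax(-v, 0)         # red removed where negative
    png::writePNG(rgb_arr, path)
  }
  invisible(img)
}

#' Top-N marker shortlist
#'
#' The `top_n` features of the global SHAP ranking, joined with lipid
#' annotations where available. Features lying an integer number of 13C mass
#' differences above an annotated feature (within tolerance) are
#' cross-referenced as its isotopes.
#'
#' @param shap An [shap_values()] result (or a [global_ranking()] table).
#' @param annotations Optional [annotate_peaks()] table for the same feature
#'   m/z values.
#' @param top_n Shortlist length (default 20).
#' @param tol_ppm Isotope cross-reference tolerance (default 7 ppm).
#' @return data.frame of class `marker_shortlist`: rank, feature_mz,
#'   tol_ppm, global_score, direction, annotation, isotope_of.
#' @export
marker_shortlist <- function(shap, annotations = NULL, top_n = 20, tol_ppm = 7) {
  ranking <- if (inherits(shap, "sdd_shap")) global_ranking(shap) else shap
  out <- utils::head(ranking, top_n)
  out$tol_ppm <- rep(tol_ppm, nrow(out))
  out$annotation <- rep(NA_character_, nrow(out))
  out$isotope_of <- rep(NA_character_, nrow(out))
  if (!is.null(annotations) && nrow(out)) {
    for (i in seq_len(nrow(out))) {
      k <- which.min(abs(annotations$feature_mz - out$feature_mz[i]))
      if (length(k) && abs(ppm_error(out$feature_mz[i], annotations$feature_mz[k])) < 0.1 &&
          annotations$name[k] != "unknown") {
        iso <- annotations$n13c[k]
        out$annotation[i] <- if (!is.na(iso) && iso > 0)
          sprintf("%s [13C x%d]", annotations$name[k], iso) else annotations$name[k]
      }
    }
    # cross-reference isotopologues of annotated monoisotopic features
    ann_mono <- annotations[!is.na(annotations$n13c) & annotations$n13c == 0 &
                              annotations$name != "unknown", , drop = FALSE]
    for (i in seq_len(nrow(out))) {
      for (k in 1:3) {
        target <- out$feature_mz[i] - k * C13_SHIFT
        j <- which(abs(ppm_error(ann_mono$feature_mz, target)) <= tol_ppm)
        if (length(j)) {
          out$isotope_of[i] <- ann_mono$name[j[1]]
          break
        }
      }
    }
  }
  out <- out[, c("rank", "feature_mz", "tol_ppm", "global_score", "direction",
                 "annotation", "isotope_of")]
  class(out) <- c("marker_shortlist", "data.frame")
  out
}

#' @export
print.marker_shortlist <- function(x, ...) {
  cat(sprintf("Top-%d SDD marker candidates by global SHAP importance:\n", nrow(x)))
  df <- as.data.frame(x)
  df$feature_mz <- sprintf("%.4f", df$feature_mz)
  df$global_score <- sprintf("%.4g", df$global_score)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
plot.sdd_shap <- function(x, top_n = 20, ...) {
  r <- utils::head(global_ranking(x), top_n)
  cols <- ifelse(r$direction == "positive", "#c23b22",
                 ifelse(r$direction == "negative", "#3b6fc2", "grey"))
  graphics::barplot(rev(r$global_score), horiz = TRUE, col = rev(cols),
                    names.arg = rev(sprintf("%.3f", r$feature_mz)),
                    las = 1, cex.names = 0.6,
                    xlab = "mean |SHAP| (log-odds)",
                    main = sprintf("Top-%d global feature importance", nrow(r)), ...)
  invisible(r)
}

# ---- brute-force Shapley oracle on small single trees -----------------------
# Used by the test suite to validate TreeSHAP output: enumerates all feature
# coalitions and computes the cover-weighted conditional expectation a tree
# assigns to a partially observed pixel, exactly as the path-dependent
# TreeSHAP algorithm defines it.

# Parse the booster's trees into a node table (xgb.model.dt.tree equivalent
# without data.table): returns list of data.frames per tree.
booster_trees <- function(booster) {
  dump <- xgboost::xgb.dump(booster, with_stats = TRUE)
  trees <- list()
  cur <- NULL
  for (line in dump) {
    if (grepl("^booster", line)) {
      if (!is.null(cur)) trees[[length(trees) + 1L]] <- cur
      cur <- data.frame(node = integer(), feature = integer(), split = numeric(),
                        yes = integer(), no = integer(), missing = integer(),
                        leaf = numeric(), cover = numeric())
      next
    }
    node <- as.integer(sub(":.*", "", gsub("^\\s+", "", line)))
    if (grepl("leaf=", line)) {
      leaf <- as.numeric(sub(".*leaf=([-0-9.e+]+).*", "\\1", line))
      cover <- as.numeric(sub(".*cover=([-0-9.e+]+).*", "\\1", line))
      cur <- rbind(cur, data.frame(node = node, feature = NA_integer_,
                                   split = NA_real_, yes = NA_integer_,
                                   no = NA_integer_, missing = NA_integer_,
                                   leaf = leaf, cover = cover))
    } else {
      feat <- sub(".*\\[f([0-9]+)<.*", "\\1", line)
      split <- as.numeric(sub(".*<([-0-9.e+]+)\\].*", "\\1", line))
      yes <- as.integer(sub(".*yes=([0-9]+).*", "\\1", line))
      no <- as.integer(sub(".*no=([0-9]+).*", "\\1", line))
      miss <- as.integer(sub(".*missing=([0-9]+).*", "\\1", line))
      cover <- as.numeric(sub(".*cover=([-0-9.e+]+).*", "\\1", line))
      cur <- rbind(cur, data.frame(node = node, feature = as.integer(feat),
                                   split = split, yes = yes, no = no,
                                   missing = miss, leaf = NA_real_,
                                   cover = cover))
    }
  }
  if (!is.null(cur)) trees[[length(trees) + 1L]] <- cur
  trees
}

# Cover-weighted conditional expectation of one tree for pixel x with only
# the features in `known` observed (path-dependent EXPVALUE recursion).
tree_expvalue <- function(tree, x, known, node = 0L) {
  row <- tree[tree$node == node, ]
  if (!is.na(row$leaf)) return(row$leaf)
  f <- row$feature + 1L          # dump indexes features from 0
  if (f %in% known) {
    nxt <- if (x[f] < row$split) row$yes else row$no
    return(tree_expvalue(tree, x, known, nxt))
  }
  cy <- tree$cover[tree$node == row$yes]
  cn <- tree$cover[tree$node == row$no]
  (cy * tree_expvalue(tree, x, known, row$yes) +
     cn * tree_expvalue(tree, x, known, row$no)) / (cy + cn)
}

#' Brute-force Shapley values of a small tree model
#'
#' Exhaustive Shapley enumeration over all `2^k` feature coalitions, with the
#' coalition value defined as the cover-weighted conditional expectation of
#' the tree ensemble (the path-dependent TreeSHAP value function). Only
#' feasible for models with few features; used to validate the exact
#' TreeSHAP computation.
#'
#' @param booster An xgboost booster (margin output).
#' @param x Numeric feature vector of one pixel.
#' @return Named list with `phi` (per-feature Shapley values) and
#'   `base_value`.
#' @export
brute_force_shapley <- function(booster, x) {
  trees <- booster_trees(booster)
  k <- length(x)
  if (k > 12) stop_sddmark("brute-force enumeration limited to <= 12 features")
  v <- function(known) {
    sum(vapply(trees, tree_expvalue, numeric(1), x = x, known = known))
  }
  subsets <- lapply(0:(2^k - 1), function(b) which(bitwAnd(b, 2^(0:(k - 1))) > 0))
  vals <- vapply(subsets, v, numeric(1))
  names(vals) <- vapply(subsets, paste, character(1), collapse = ",")
  phi <- numeric(k)
  for (j in seq_len(k)) {
    for (si in seq_along(subsets)) {
      S <- subsets[[si]]
      if (j %in% S) next
      s <- length(S)
      w <- factorial(s) * factorial(k - s - 1) / factorial(k)
      with_j <- paste(sort(c(S, j)), collapse = ",")
      phi[j] <- phi[j] + w * (vals[[with_j]] - vals[[si]])
    }
  }
  list(phi = phi, base_value = v(integer()))
}
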