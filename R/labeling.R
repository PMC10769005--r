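# Training-label creation: non-negative matrix factorization of the feature
# matrix yields latent spatial patterns; the deposit-like pattern is
# thresholded into a positive (SDD) mask, with a manual-correction hook; the
# negative (background) class is sampled from the remaining pixels so the
# classes are balanced.

#' Label mask constructor
#'
#' @param labels Character matrix (`grid_height x grid_width`) with values in
#'   `{SDD, background, unlabeled}`.
#' @param source Provenance: `"nmf"`, `"file"` or `"manual-correction"`.
#' @return Object of class `label_mask` with per-class `counts`.
#' @export
new_label_mask <- function(labels, source = "nmf") {
  stopifnot(is.matrix(labels),
            all(labels %in% c("SDD", "background", "unlabeled")))
  counts <- c(SDD = sum(labels == "SDD"),
              background = sum(labels == "background"),
              unlabeled = sum(labels == "unlabeled"))
  structure(list(labels = labels, source = source, counts = counts),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask> %d x %d (%s): %d SDD, %d background, %d unlabeled\n",
              ncol(x$labels), nrow(x$labels), x$source,
              x$counts[["SDD"]], x$counts[["background"]], x$counts[["unlabeled"]]))
  invisible(x)
}

#' Non-negative matrix factorization of a feature matrix
#'
#' Seeded multiplicative-update NMF (Lee-Seung, Frobenius objective) of the
#' pixels-by-features intensity table. Spatial scores (W) and spectral
#' loadings (H) are non-negative; the factorization is deterministic given
#' the seed.
#'
#' @param matrix A normalized `feature_matrix` (a plain numeric matrix is
#'   also accepted).
#' @param rank Number of latent components (>= 1).
#' @param seed Integer seed for the random non-negative initialization.
#' @param max_iter Maximum multiplicative updates (default 200).
#' @param tol Relative-change convergence tolerance on the reconstruction
#'   error (default 1e-5).
#' @param winsorize Column-wise winsorization quantile applied before the
#'   factorization (default 0.999) so that single-pixel outlier spikes cannot
#'   dominate the Frobenius objective; `NULL` disables it.
#' @param init `"nndsvd"` (default) for the deterministic SVD-based
#'   non-negative initialization, or `"random"` for a seeded uniform start.
#' @return Object of class `ims_nmf` with `spatial_scores` (pixels x rank),
#'   `spectral_loadings` (rank x features), `reconstruction_error`, `seed`.
#' @export
nmf_patterns <- function(matrix, rank = 8, seed = 1, max_iter = 200, tol = 1e-5,
                         winsorize = 0.999, init = c("nndsvd", "random")) {
  init <- match.arg(init)
  fm <- NULL
  if (inherits(matrix, "feature_matrix")) {
    fm <- matrix
    matrix <- fm$values
  }
  stopifnot(is.matrix(matrix), all(matrix >= 0), rank >= 1)
  if (!is.null(winsorize)) {
    caps <- apply(matrix, 2, stats::quantile, probs = winsorize, names = FALSE)
    matrix <- pmin(matrix, matrix(caps, nrow = nrow(matrix), ncol = ncol(matrix),
                                  byrow = TRUE))
  }
  if (rank > min(dim(matrix)))
    stop_sddmark("rank %d exceeds min(pixels, features) = %d", rank, min(dim(matrix)))
  n <- nrow(matrix); m <- ncol(matrix)
  # columns emptied by winsorization (single-pixel artefacts) carry no
  # pattern information; factor the active columns only
  active <- which(colSums(matrix) > 0)
  V <- matrix[, active, drop = FALSE]
  ma <- length(active)
  if (rank > ma) stop_sddmark("rank %d exceeds the number of non-empty features (%d)",
                              rank, ma)
  eps <- 1e-10
  if (identical(init, "nndsvd")) {
    sv <- svd(V, nu = rank, nv = rank)
    W <- base::matrix(0, n, rank); H <- base::matrix(0, rank, ma)
    W[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
    H[1, ] <- sqrt(sv$d[1]) * abs(sv$v[, 1])
    for (j in seq_len(rank)[-1]) {
      u <- sv$u[, j]; v <- sv$v[, j]
      up <- pmax(u, 0); un <- pmax(-u, 0)
      vp <- pmax(v, 0); vn <- pmax(-v, 0)
      nup <- sqrt(sum(up^2)); nun <- sqrt(sum(un^2))
      nvp <- sqrt(sum(vp^2)); nvn <- sqrt(sum(vn^2))
      if (nup * nvp >= nun * nvn && nup * nvp > 0) {
        s <- sqrt(sv$d[j] * nup * nvp)
        W[, j] <- s * up / nup; H[j, ] <- s * vp / nvp
      } else if (nun * nvn > 0) {
        s <- sqrt(sv$d[j] * nun * nvn)
        W[, j] <- s * un / nun; H[j, ] <- s * vn / nvn
      }
    }
    fill <- mean(V) / 100
    W[W < fill] <- fill; H[H < fill] <- fill
  } else {
    scale0 <- sqrt(mean(V) / rank)
    with_seed(child_seed(seed, "nmf"), {
      W <- Matrix_runif(n, rank, scale0)
      H <- Matrix_runif(rank, ma, scale0)
    })
  }
  err_prev <- Inf
  nrmV <- norm(V, "F")
  for (it in seq_len(max_iter)) {
    H <- H * crossprod(W, V) / (crossprod(W) %*% H + eps)
    W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
    if (it %% 10 == 0 || it == max_iter) {
      err <- norm(V - W %*% H, "F") / nrmV
      if (is.finite(err_prev) && abs(err_prev - err) < tol * max(err, eps)) {
        err_prev <- err
        break
      }
      err_prev <- err
    }
  }
  if (!is.finite(err_prev)) err_prev <- norm(V - W %*% H, "F") / nrmV
  H_full <- base::matrix(0, nrow = rank, ncol = m)
  H_full[, active] <- H
  structure(list(rank = rank, spatial_scores = W, spectral_loadings = H_full,
                 reconstruction_error = err_prev, seed = seed,
                 pixel_index = if (!is.null(fm)) fm$pixel_index else NULL,
                 grid_shape = if (!is.null(fm)) fm$grid_shape else NULL),
            class = "ims_nmf")
}

Matrix_runif <- function(n, m, scale) {
  matrix(stats::runif(n * m, 0, 2 * scale), nrow = n, ncol = m)
}

#' @export
print.ims_nmf <- function(x, ...) {
  cat(sprintf("<ims_nmf> rank %d, relative reconstruction error %.4f\n",
              x$rank, x$reconstruction_error))
  invisible(x)
}

# Render component scores as a grid image.
component_image <- function(nmf, component) {
  stopifnot(component >= 1, component <= nmf$rank)
  if (is.null(nmf$grid_shape))
    stop_sddmark("NMF was fitted on a bare matrix without pixel coordinates")
  img <- matrix(0, nrow = nmf$grid_shape[2], ncol = nmf$grid_shape[1])
  img[cbind(nmf$pixel_index[, 2] + 1L, nmf$pixel_index[, 1] + 1L)] <-
    nmf$spatial_scores[, component]
  img
}

# Spatial compactness of a binary mask: mean fraction of 4-neighbours of
# positive pixels that are also positive. High for contiguous blobs, low for
# scattered pixels.
mask_compactness <- function(mask) {
  if (!any(mask)) return(0)
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- mask
  neigh <- pad[1:h, 2:(w + 1)] + pad[3:(h + 2), 2:(w + 1)] +
    pad[2:(h + 1), 1:w] + pad[2:(h + 1), 3:(w + 2)]
  mean(neigh[mask]) / 4
}

# Lesion-likeness of a thresholded component mask. Dome-shaped deposits form
# contiguous blobs (high compactness) whose per-column height varies strongly
# (domes rise and fall along the tissue) and whose component scores are
# near-zero outside the mask (high in/out contrast). Tissue strata are
# grid-spanning bands of near-constant height; their complements (band minus
# lesions) vary in height but have diffuse scores; noise components are
# scattered. Score = compactness x column-height CV x sqrt(contrast).
mask_lesion_score <- function(mask, scores = NULL) {
  if (!any(mask) || all(mask)) return(0)
  heights <- colSums(mask)
  cv <- if (mean(heights) > 0) stats::sd(heights) / mean(heights) else 0
  contrast <- if (is.null(scores)) 1 else
    mean(scores[mask]) / max(mean(scores[!mask]), 1e-9)
  mask_compactness(mask) * cv * sqrt(max(contrast, 0))
}

# Otsu's threshold on a numeric vector (256-bin histogram).
otsu_threshold <- function(v) {
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = 257)
  h <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE), nbins = 256)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (breaks[-1] + breaks[-257]) / 2
  mu <- cumsum(p * mids)
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

#' Build an SDD mask from an NMF spatial pattern
#'
#' Pixels whose score on the chosen component exceeds a threshold are labeled
#' `SDD`; the rest `background`. By default the component is auto-selected as
#' the one whose thresholded mask looks most lesion-like: contiguous,
#' near-round blobs (deposit domes), as opposed to grid-spanning ribbons
#' (tissue strata) or noise-scattered pixels. The threshold is Otsu's method
#' on the component scores; a fixed `threshold_quantile` can be given
#' instead. A correction
#' mask (from file or manual editing) can remove or add positive pixels.
#'
#' @param nmf An [nmf_patterns()] result fitted on a `feature_matrix`.
#' @param component Component index, or `NULL` to auto-select.
#' @param threshold_quantile Score quantile in `[0, 1]` used as threshold, or
#'   `NULL` (default) for Otsu's method.
#' @param correction Optional `label_mask` whose `SDD`/`background` entries
#'   override the pattern-derived labels.
#' @return A `label_mask` (source `"nmf"`, or `"manual-correction"` if a
#'   correction was applied), with the chosen component and threshold in
#'   attributes.
#' @export
mask_from_pattern <- function(nmf, component = NULL, threshold_quantile = NULL,
                              correction = NULL) {
  stopifnot(inherits(nmf, "ims_nmf"))
  pick_mask <- function(cmp) {
    scores <- nmf$spatial_scores[, cmp]
    thr <- if (is.null(threshold_quantile)) otsu_threshold(scores)
           else stats::quantile(scores, threshold_quantile, names = FALSE)
    if (!is.null(threshold_quantile) && threshold_quantile >= 1) thr <- Inf
    scores > thr
  }
  if (is.null(component)) {
    comp_scores <- vapply(seq_len(nmf$rank), function(cmp) {
      pos <- pick_mask(cmp)
      at <- cbind(nmf$pixel_index[, 2] + 1L, nmf$pixel_index[, 1] + 1L)
      img <- matrix(FALSE, nrow = nmf$grid_shape[2], ncol = nmf$grid_shape[1])
      img[at] <- pos
      sc <- matrix(0, nrow = nmf$grid_shape[2], ncol = nmf$grid_shape[1])
      sc[at] <- nmf$spatial_scores[, cmp]
      mask_lesion_score(img, sc)
    }, numeric(1))
    component <- which.max(comp_scores)
  }
  if (component > nmf$rank) stop_sddmark("component %d > rank %d", component, nmf$rank)
  pos <- pick_mask(component)
  if (!any(pos)) warning("threshold above the maximum score: empty positive set",
                         call. = FALSE)
  labels <- matrix("unlabeled", nrow = nmf$grid_shape[2], ncol = nmf$grid_shape[1])
  at <- cbind(nmf$pixel_index[, 2] + 1L, nmf$pixel_index[, 1] + 1L)
  labels[at] <- ifelse(pos, "SDD", "background")
  src <- "nmf"
  if (!is.null(correction)) {
    stopifnot(inherits(correction, "label_mask"))
    override <- correction$labels != "unlabeled"
    labels[override] <- correction$labels[override]
    src <- "manual-correction"
  }
  out <- new_label_mask(labels, source = src)
  attr(out, "component") <- component
  out
}

#' Balanced SDD/background training labels
#'
#' Positives are the `SDD` pixels of the mask; negatives are drawn uniformly
#' without replacement from all non-positive pixels (SDD pixels can never
#' enter the background class), matching the positive count when possible.
#'
#' @param mask A `label_mask`.
#' @param seed Integer seed for the negative sampling.
#' @param ratio Target `|negatives| / |positives|` (default 1).
#' @return Object of class `training_labels` with 0-based `positive` and
#'   `negative` coordinate matrices, the seed, and the achieved
#'   `balance_ratio`.
#' @export
balance_labels <- function(mask, seed = 1, ratio = 1) {
  stopifnot(inherits(mask, "label_mask"))
  h <- nrow(mask$labels); w <- ncol(mask$labels)
  pos_idx <- which(mask$labels == "SDD")
  neg_pool <- which(mask$labels != "SDD")
  if (!length(pos_idx)) stop_sddmark("no positive (SDD) pixels in the mask")
  if (!length(neg_pool)) stop_sddmark("no non-positive pixels to sample from")
  n_neg <- round(length(pos_idx) * ratio)
  if (length(neg_pool) < n_neg) {
    warning(sprintf("only %d non-positive pixels available (wanted %d); using all",
                    length(neg_pool), n_neg), call. = FALSE)
    n_neg <- length(neg_pool)
  }
  neg_idx <- with_seed(child_seed(seed, "balance"),
                       sample(neg_pool, n_neg, replace = FALSE))
  to_coords <- function(idx) {
    cbind(x = (idx - 1L) %/% h, y = (idx - 1L) %% h)   # matrices are row=y
  }
  structure(list(positive = to_coords(pos_idx), negative = to_coords(sort(neg_idx)),
                 seed = seed,
                 balance_ratio = n_neg / length(pos_idx)),
            class = "training_labels")
}

#' @export
print.training_labels <- function(x, ...) {
  cat(sprintf("<training_labels> %d positive, %d negative (ratio %.2f)\n",
              nrow(x$positive), nrow(x$negative), x$balance_ratio))
  invisible(x)
}

#' Dice overlap coefficient between two binary masks
#'
#' `2|A & B| / (|A| + |B|)`; 1 for identical masks.
#'
#' @param a,b Logical matrices of equal shape.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
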