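# Spectral preprocessing chain: alignment-peak selection, per-pixel scalar
# ppm alignment, >=4-point linear ppm calibration, geometric common mass
# axis, mean-spectrum peak picking, feature extraction and robust 5-95
# percentile TIC normalization.

#' Geometric common mass axis
#'
#' Bin edges satisfy `edges[i+1] = edges[i] * (1 + spacing_ppm * 1e-6)`, i.e.
#' constant relative (ppm) spacing, starting at `mz_min`.
#'
#' @param mz_min,mz_max Axis range (0 < mz_min <= mz_max).
#' @param spacing_ppm Relative spacing between adjacent edges in ppm
#'   (default 1.5).
#' @return Object of class `mass_axis` with fields `edges`, `spacing_ppm`,
#'   `mz_range`.
#' @export
build_common_axis <- function(mz_min, mz_max, spacing_ppm = 1.5) {
  stopifnot(mz_min > 0, mz_max >= mz_min)
  if (spacing_ppm <= 0) stop_sddmark("spacing_ppm must be positive")
  r <- spacing_ppm * 1e-6
  n_bins <- if (mz_max == mz_min) 0L else ceiling(log(mz_max / mz_min) / log1p(r))
  edges <- mz_min * (1 + r)^(0:n_bins)
  structure(list(edges = edges, spacing_ppm = spacing_ppm,
                 mz_range = c(mz_min, mz_max)),
            class = "mass_axis")
}

#' @export
print.mass_axis <- function(x, ...) {
  cat(sprintf("<mass_axis> %d edges, %g-%g, %.3g ppm spacing\n",
              length(x$edges), x$mz_range[1], x$mz_range[2], x$spacing_ppm))
  invisible(x)
}

# Bin index of each m/z on a geometric axis (0 for out-of-range-left,
# length(edges) for beyond the last edge). Log arithmetic instead of
# findInterval keeps this O(1) per peak on a megascale axis.
axis_bin <- function(mz, axis) {
  r <- axis$spacing_ppm * 1e-6
  idx <- floor(log(mz / axis$edges[1]) / log1p(r)) + 1
  # guard against log round-off at edges
  nb <- length(axis$edges) - 1L
  idx[mz < axis$edges[1]] <- 0
  idx <- pmin(pmax(idx, ifelse(mz >= axis$edges[1], 1, 0)), nb + 1)
  hi <- which(idx >= 1 & idx <= nb)
  if (length(hi)) {
    e <- axis$edges
    wrong_hi <- hi[mz[hi] >= e[pmin(idx[hi] + 1, nb + 1)]]
    idx[wrong_hi] <- idx[wrong_hi] + 1
    wrong_lo <- hi[mz[hi] < e[idx[hi]]]
    idx[wrong_lo] <- idx[wrong_lo] - 1
  }
  as.integer(idx)
}

# Bin-centre m/z (geometric mean of edges).
axis_centers <- function(axis) {
  e <- axis$edges
  sqrt(e[-length(e)] * e[-1])
}

#' Resample a centroid spectrum onto a common axis
#'
#' Each centroid's intensity is added to the bin containing its m/z;
#' out-of-range peaks are dropped (count attached as attribute). Total
#' in-range intensity is conserved exactly.
#'
#' @param mz,intensity Centroid peak list.
#' @param axis A [build_common_axis()] axis.
#' @return Dense intensity vector of length `length(edges) - 1`, with
#'   attribute `n_dropped`.
#' @export
resample_spectrum <- function(mz, intensity, axis) {
  nb <- length(axis$edges) - 1L
  out <- numeric(nb)
  idx <- axis_bin(mz, axis)
  keep <- idx >= 1L & idx <= nb
  if (any(keep)) {
    agg <- rowsum(intensity[keep], idx[keep])
    out[as.integer(rownames(agg))] <- agg[, 1]
  }
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Mean spectrum of one or more datasets on a common axis
#'
#' Arithmetic mean over all pixels of all supplied datasets, after binning
#' each spectrum on `axis`.
#'
#' @param datasets An `ims_dataset` or list of them (shared polarity).
#' @param axis A `mass_axis`.
#' @return Numeric vector of mean binned intensities.
#' @export
mean_spectrum <- function(datasets, axis) {
  if (inherits(datasets, "ims_dataset")) datasets <- list(datasets)
  pol <- unique(vapply(datasets, function(d) d$polarity, character(1)))
  if (length(pol) != 1) stop_sddmark("datasets have mixed polarity")
  nb <- length(axis$edges) - 1L
  acc <- numeric(nb)
  n_pix <- 0L
  for (d in datasets) {
    n_pix <- n_pix + length(d)
    idx <- axis_bin(unlist(d$mz, use.names = FALSE), axis)
    ints <- unlist(d$intensity, use.names = FALSE)
    keep <- idx >= 1L & idx <= nb
    if (any(keep)) {
      agg <- rowsum(ints[keep], idx[keep])
      at <- as.integer(rownames(agg))
      acc[at] <- acc[at] + agg[, 1]
    }
  }
  acc / max(1L, n_pix)
}

#' Peak-pick an average spectrum
#'
#' Local maxima of the binned average spectrum above a noise-derived
#' threshold (`snr_threshold` x the MAD-estimated noise of the nonzero bins)
#' and a minimum-prominence criterion. The apex m/z is reported as the
#' intensity-weighted centroid over the apex bin +/- 1. Isotopic peaks are
#' retained.
#'
#' @param avg_spectrum Binned mean spectrum (vector on `axis`).
#' @param axis The `mass_axis` the spectrum lives on.
#' @param snr_threshold Signal-to-noise multiple of the MAD noise (default 3).
#' @param min_prominence Minimum absolute apex intensity (default 0).
#' @param min_rel_prominence Minimum apex intensity relative to the base peak
#'   of the average spectrum (default 1e-3). Suppresses spurious apexes
#'   contributed by a handful of pixels (e.g. spectra that could not be
#'   aligned), which would otherwise fragment the feature windows of genuine
#'   species.
#' @return Sorted numeric vector of picked feature m/z values, with the apex
#'   intensities attached as attribute `intensity`.
#' @export
pick_peaks <- function(avg_spectrum, axis, snr_threshold = 3, min_prominence = 0,
                       min_rel_prominence = 1e-3) {
  nb <- length(avg_spectrum)
  stopifnot(nb == length(axis$edges) - 1L)
  nz <- avg_spectrum[avg_spectrum > 0]
  if (!length(nz)) return(structure(numeric(), intensity = numeric()))
  # Centroided data carry no baseline: most bins are exactly zero, so the MAD
  # over all bins estimates the additive noise floor (zero in its absence).
  noise <- stats::mad(avg_spectrum)
  thr <- max(snr_threshold * noise, min_prominence,
             min_rel_prominence * max(avg_spectrum), .Machine$double.eps)
  cand <- which(avg_spectrum >= thr)
  if (!length(cand)) return(structure(numeric(), intensity = numeric()))
  v <- avg_spectrum
  left  <- ifelse(cand > 1, v[cand - 1L], 0)
  right <- ifelse(cand < nb, v[cand + 1L], 0)
  # local maximum; plateaus/shoulders resolved toward the left bin
  apex <- cand[v[cand] > left & v[cand] >= right]
  if (!length(apex)) return(structure(numeric(), intensity = numeric()))
  centers <- axis_centers(axis)
  mz_apex <- vapply(apex, function(i) {
    win <- max(1L, i - 1L):min(nb, i + 1L)
    sum(centers[win] * v[win]) / sum(v[win])
  }, numeric(1))
  o <- order(mz_apex)
  structure(mz_apex[o], intensity = v[apex][o])
}

#' Select internal alignment reference peaks
#'
#' Candidates are the peaks of the un-aligned mean spectrum; each candidate's
#' occupancy is the fraction of pixels containing a centroid within
#' `tol_ppm`. The `n_peaks` most-occupied candidates with occupancy at least
#' `min_fraction` are returned, greedily enforcing a minimum mutual spacing
#' so the references span the m/z range.
#'
#' @param dataset An `ims_dataset`.
#' @param n_peaks Number of reference peaks (default 6).
#' @param min_fraction Minimum pixel occupancy (default 0.5).
#' @param tol_ppm Occupancy matching tolerance in ppm (default 25, wide
#'   enough to tolerate the un-corrected drift).
#' @param min_spacing Minimum mutual spacing between references in Th
#'   (default 50).
#' @param axis Optional pre-built axis for the mean spectrum.
#' @return list with `reference_peaks` (m/z), `occupancy`, and the candidate
#'   table; class `alignment_model`.
#' @export
select_alignment_peaks <- function(dataset, n_peaks = 6, min_fraction = 0.5,
                                   tol_ppm = 25, min_spacing = 50,
                                   axis = NULL) {
  stopifnot(inherits(dataset, "ims_dataset"), length(dataset) > 0)
  if (is.null(axis))
    axis <- build_common_axis(dataset$mz_range[1], dataset$mz_range[2], 1.5)
  avg <- mean_spectrum(dataset, axis)
  cand_mz <- pick_peaks(avg, axis)
  if (!length(cand_mz)) stop_sddmark("no candidate peaks in the mean spectrum")
  occ <- peak_occupancy(dataset, cand_mz, tol_ppm)
  ok <- occ >= min_fraction
  cand <- data.frame(mz = cand_mz[ok], occupancy = occ[ok])
  cand <- cand[order(cand$mz), , drop = FALSE]
  # left-to-right greedy maximizes how many spaced references exist; any
  # occupancy-ordered greedy can strand itself inside a cluster of peaks
  chosen <- integer()
  last <- -Inf
  for (i in seq_len(nrow(cand))) {
    if (cand$mz[i] - last >= min_spacing) {
      chosen <- c(chosen, i)
      last <- cand$mz[i]
    }
  }
  if (length(chosen) < n_peaks)
    stop_sddmark("only %d candidate peaks meet occupancy >= %.2f (need %d)",
                 length(chosen), min_fraction, n_peaks)
  if (length(chosen) > n_peaks)
    chosen <- chosen[order(-cand$occupancy[chosen])[seq_len(n_peaks)]]
  sel <- cand[sort(chosen), , drop = FALSE]
  refs <- sel$mz
  # refinement pass: an apex of the un-aligned (drift-smeared) mean spectrum
  # can sit several ppm from its species' drift-median position, with an
  # offset that differs per reference; re-centre each reference on the median
  # of its uniquely matched per-pixel positions so all references carry the
  # same (global) offset and the per-pixel shift estimate becomes consistent
  refs <- refine_reference_peaks(dataset, refs, tol_ppm)
  structure(list(reference_peaks = refs, occupancy = sel$occupancy,
                 candidates = data.frame(mz = cand_mz, occupancy = occ),
                 tol_ppm = tol_ppm),
            class = "alignment_model")
}

refine_reference_peaks <- function(dataset, refs, tol_ppm) {
  errs <- vector("list", length(refs))
  for (r in seq_along(refs)) errs[[r]] <- numeric(0)
  for (i in seq_along(dataset$mz)) {
    mz <- dataset$mz[[i]]
    if (!length(mz)) next
    for (r in seq_along(refs)) {
      win <- refs[r] * tol_ppm * 1e-6
      lo <- findInterval(refs[r] - win, mz)
      hi <- findInterval(refs[r] + win, mz)
      if (hi - lo == 1L)
        errs[[r]] <- c(errs[[r]], ppm_error(mz[hi], refs[r]))
    }
  }
  adj <- vapply(errs, function(e) if (length(e)) stats::median(e) else 0, numeric(1))
  refs * (1 + adj * 1e-6)
}

# Fraction of pixels containing a centroid within tol_ppm of each query m/z.
peak_occupancy <- function(dataset, query_mz, tol_ppm) {
  counts <- numeric(length(query_mz))
  for (i in seq_along(dataset$mz)) {
    mz <- dataset$mz[[i]]
    if (!length(mz)) next
    pos <- findInterval(query_mz, mz)
    lo <- pmax(pos, 1L)
    hi <- pmin(pos + 1L, length(mz))
    d <- pmin(abs(mz[lo] - query_mz), abs(mz[hi] - query_mz))
    counts <- counts + (d / query_mz * 1e6 <= tol_ppm)
  }
  counts / length(dataset$mz)
}

#' Align every pixel to the internal reference peaks
#'
#' For each pixel, each reference peak is matched to the nearest centroid
#' within `max_shift_ppm`; the pixel's scalar ppm shift is the median of the
#' matched ppm deviations and is removed via `mz <- mz / (1 + shift * 1e-6)`.
#' Pixels with fewer than 2 matched references are left unchanged (shift 0)
#' with a warning.
#'
#' @param dataset An `ims_dataset`.
#' @param reference_peaks Reference m/z values (or an `alignment_model`).
#' @param max_shift_ppm Maximum shift searched (default 25 ppm).
#' @return list with `dataset` (aligned) and `shift_ppm` (per-pixel vector).
#' @export
align_dataset <- function(dataset, reference_peaks, max_shift_ppm = 25) {
  if (inherits(reference_peaks, "alignment_model"))
    reference_peaks <- reference_peaks$reference_peaks
  n <- length(dataset)
  shifts <- numeric(n)
  n_unmatched <- 0L
  for (i in seq_len(n)) {
    fit <- align_pixel_shift(dataset$mz[[i]], reference_peaks, max_shift_ppm)
    if (is.na(fit)) {
      n_unmatched <- n_unmatched + 1L
      fit <- 0
    }
    shifts[i] <- fit
    if (fit != 0) dataset$mz[[i]] <- dataset$mz[[i]] / (1 + fit * 1e-6)
  }
  if (n_unmatched > 0)
    warning(sprintf("%d pixel(s) matched <2 reference peaks; left unaligned",
                    n_unmatched), call. = FALSE)
  list(dataset = dataset, shift_ppm = shifts)
}

#' @rdname align_dataset
#' @param mz Sorted m/z vector of one pixel.
#' @return `align_pixel_shift()` returns the estimated scalar shift in ppm,
#'   or `NA` if fewer than 2 references matched.
#' @export
align_pixel_shift <- function(mz, reference_peaks, max_shift_ppm = 25) {
  if (!length(mz)) return(NA_real_)
  # a reference counts only when exactly one centroid lies inside its search
  # window: ambiguous references (two species within the window, e.g. an
  # isotopologue of one species near the monoisotopic peak of another) would
  # otherwise flip between neighbours and corrupt the shift estimate
  errs <- vapply(reference_peaks, function(rp) {
    win <- rp * max_shift_ppm * 1e-6
    lo <- findInterval(rp - win, mz)
    hi <- findInterval(rp + win, mz)
    if (hi - lo != 1L) return(NA_real_)   # 0 or >1 centroids in the window
    ppm_error(mz[hi], rp)
  }, numeric(1))
  errs <- errs[!is.na(errs)]
  if (length(errs) < 2) return(NA_real_)
  stats::median(errs)
}

#' Calibrate a dataset against known reference ions
#'
#' Matches each calibrant's theoretical m/z in the (aligned) mean spectrum
#' within `search_ppm`, fits the ppm-error model `err(mz) = a + b * mz` by
#' least squares over the matched calibrants (at least 4 required), and
#' applies the inverse correction `mz <- mz / (1 + err(mz) * 1e-6)` to every
#' spectrum.
#'
#' @param dataset An `ims_dataset` (already aligned).
#' @param calibrants Numeric vector of theoretical calibrant m/z values, or a
#'   data.frame with a `theoretical_mz` column (e.g. [calibrant_table()]).
#' @param search_ppm Matching window in ppm (default 20).
#' @param axis Optional pre-built `mass_axis`.
#' @return list with `dataset` (calibrated) and `model` (class
#'   `calibration_model`: coefficients, matched calibrants, residual_ppm).
#' @export
calibrate <- function(dataset, calibrants, search_ppm = 20, axis = NULL) {
  if (is.data.frame(calibrants)) calibrants <- calibrants$theoretical_mz
  stopifnot(length(calibrants) >= 4)
  if (is.null(axis))
    axis <- build_common_axis(dataset$mz_range[1], dataset$mz_range[2], 1.5)
  avg <- mean_spectrum(dataset, axis)
  peaks <- pick_peaks(avg, axis)
  if (!length(peaks)) stop_sddmark("no peaks found in the mean spectrum")
  pk_int <- attr(peaks, "intensity")
  # match each calibrant to the most intense picked peak inside the search
  # window (a nearest-by-ppm rule can latch onto spurious low-intensity
  # apexes left by the few unalignable pixels)
  obs <- vapply(calibrants, function(cm) {
    inside <- which(abs(ppm_error(peaks, cm)) <= search_ppm)
    if (!length(inside)) return(NA_real_)
    peaks[inside[which.max(pk_int[inside])]]
  }, numeric(1))
  matched <- !is.na(obs)
  if (sum(matched) < 4)
    stop_sddmark("only %d of %d calibrants matched within %.1f ppm (need >= 4)",
                 sum(matched), length(calibrants), search_ppm)
  theo <- calibrants[matched]
  err <- ppm_error(obs[matched], theo)
  fit <- stats::lm.fit(cbind(1, theo), err)
  coefs <- fit$coefficients
  correct <- function(mz) mz / (1 + (coefs[1] + coefs[2] * mz) * 1e-6)
  for (i in seq_along(dataset$mz))
    dataset$mz[[i]] <- correct(dataset$mz[[i]])
  resid_ppm <- ppm_error(correct(obs[matched]), theo)
  if (max(abs(resid_ppm)) > 5)
    warning(sprintf("post-calibration residual up to %.1f ppm", max(abs(resid_ppm))),
            call. = FALSE)
  model <- structure(list(calibrant_mz = theo, observed_mz = obs[matched],
                          coefficients = c(intercept_ppm = unname(coefs[1]),
                                           slope_ppm_per_mz = unname(coefs[2])),
                          residual_ppm = resid_ppm,
                          median_abs_residual_ppm = stats::median(abs(resid_ppm)),
                          n_matched = sum(matched)),
                     class = "calibration_model")
  list(dataset = dataset, model = model)
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> %d calibrants, err(mz) = %.3f + %.3g*mz ppm\n",
              x$n_matched, x$coefficients[1], x$coefficients[2]))
  cat(sprintf("  median |residual| = %.3f ppm\n", x$median_abs_residual_ppm))
  invisible(x)
}

#' Extract a pixels-by-features intensity matrix
#'
#' Entry (pixel, feature) is the summed intensity of that pixel's centroids
#' within `tol_ppm` of the feature m/z; windows are clipped at the midpoints
#' between adjacent features so no centroid is counted twice.
#'
#' @param dataset A calibrated `ims_dataset`.
#' @param feature_mz Sorted vector of picked feature m/z values.
#' @param tol_ppm Extraction half-window in ppm (default 7).
#' @return Object of class `feature_matrix`.
#' @export
extract_features <- function(dataset, feature_mz, tol_ppm = 7) {
  feature_mz <- as.numeric(feature_mz)
  if (anyDuplicated(feature_mz)) stop_sddmark("duplicate feature m/z values")
  if (is.unsorted(feature_mz)) feature_mz <- sort(feature_mz)
  n <- length(dataset)
  m <- length(feature_mz)
  vals <- matrix(0, nrow = n, ncol = m)
  for (i in seq_len(n)) {
    mz <- dataset$mz[[i]]
    if (!length(mz)) next
    pos <- findInterval(mz, feature_mz)
    lo <- pmax(pos, 1L)
    hi <- pmin(pos + 1L, m)
    nearest <- ifelse(abs(mz - feature_mz[lo]) <= abs(mz - feature_mz[hi]), lo, hi)
    keep <- abs(ppm_error(mz, feature_mz[nearest])) <= tol_ppm
    if (any(keep)) {
      agg <- rowsum(dataset$intensity[[i]][keep], nearest[keep])
      vals[i, as.integer(rownames(agg))] <- agg[, 1]
    }
  }
  structure(list(values = vals, feature_mz = feature_mz,
                 feature_tol_ppm = tol_ppm,
                 pixel_index = dataset$coords,
                 grid_shape = dataset$grid_shape,
                 normalized = FALSE, norm_factors = NULL),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d pixels x %d features (+/-%g ppm windows)%s\n",
              nrow(x$values), ncol(x$values), x$feature_tol_ppm,
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Robust 5-95 percentile TIC normalization
#'
#' For each pixel the robust TIC is the sum of that pixel's intensities lying
#' between its own 5th and 95th intensity percentiles; each pixel is scaled
#' by `median(robust TIC) / robust TIC(pixel)`. Intensities outside the
#' percentile window do not contribute to the TIC sum but are rescaled by the
#' pixel factor, preserving within-pixel peak ratios.
#'
#' @param x A `feature_matrix` or `ims_dataset`.
#' @param lower,upper Percentile window (defaults 0.05 and 0.95).
#' @return The normalized object, with per-pixel factors stored in
#'   `norm_factors` (feature_matrix) or attached as attribute `norm_factors`
#'   (ims_dataset).
#' @export
robust_tic_normalize <- function(x, lower = 0.05, upper = 0.95) {
  UseMethod("robust_tic_normalize")
}

robust_tic <- function(v, lower, upper) {
  # percentiles are taken over the pixel's observed (nonzero) intensities:
  # empty feature cells are not measurements
  v <- v[v > 0]
  if (!length(v)) return(0)
  q <- stats::quantile(v, c(lower, upper), names = FALSE, type = 7)
  sum(v[v >= q[1] & v <= q[2]])
}

#' @export
robust_tic_normalize.feature_matrix <- function(x, lower = 0.05, upper = 0.95) {
  tic <- apply(x$values, 1, robust_tic, lower = lower, upper = upper)
  zero <- tic == 0
  if (any(zero))
    warning(sprintf("%d pixel(s) with all-zero intensities; factor set to 1",
                    sum(zero)), call. = FALSE)
  target <- stats::median(tic[!zero])
  factors <- ifelse(zero, 1, target / tic)
  x$values <- x$values * factors
  x$normalized <- TRUE
  x$norm_factors <- factors
  x
}

#' @export
robust_tic_normalize.ims_dataset <- function(x, lower = 0.05, upper = 0.95) {
  tic <- vapply(x$intensity, robust_tic, numeric(1), lower = lower, upper = upper)
  zero <- tic == 0
  if (any(zero))
    warning(sprintf("%d pixel(s) with all-zero intensities; factor set to 1",
                    sum(zero)), call. = FALSE)
  target <- stats::median(tic[!zero])
  factors <- ifelse(zero, 1, target / tic)
  for (i in seq_along(x$intensity))
    x$intensity[[i]] <- x$intensity[[i]] * factors[i]
  attr(x, "norm_factors") <- factors
  x
}

#' Run the full spectral preprocessing chain
#'
#' Alignment-peak selection, per-pixel alignment, calibration, mean-spectrum
#' peak picking on the common axis, feature extraction and robust TIC
#' normalization, in the order of the acquisition workflow.
#'
#' @param dataset An `ims_dataset`.
#' @param calibrants Calibrant m/z values (or table); `NULL` skips calibration.
#' @param axis_ppm Common-axis spacing in ppm (default 1.5).
#' @param n_align_peaks,min_fraction Alignment-peak selection parameters
#'   (defaults 6 and 0.5).
#' @param tol_ppm Feature extraction half-window (default 7).
#' @param snr_threshold Peak-picking SNR multiple (default 3).
#' @return list with `matrix` (normalized `feature_matrix`), `feature_mz`,
#'   `alignment` (model + shifts), `calibration` model, `axis`, and the
#'   picked-peak count `n_peaks`.
#' @export
preprocess_dataset <- function(dataset, calibrants = NULL, axis_ppm = 1.5,
                               n_align_peaks = 6, min_fraction = 0.5,
                               tol_ppm = 7, snr_threshold = 3) {
  axis <- build_common_axis(dataset$mz_range[1], dataset$mz_range[2], axis_ppm)
  align_model <- select_alignment_peaks(dataset, n_peaks = n_align_peaks,
                                        min_fraction = min_fraction, axis = axis)
  aligned <- align_dataset(dataset, align_model)
  calib_model <- NULL
  ds <- aligned$dataset
  if (!is.null(calibrants)) {
    cal <- calibrate(ds, calibrants, axis = axis)
    ds <- cal$dataset
    calib_model <- cal$model
  }
  avg <- mean_spectrum(ds, axis)
  feature_mz <- pick_peaks(avg, axis, snr_threshold = snr_threshold)
  fm <- extract_features(ds, as.numeric(feature_mz), tol_ppm = tol_ppm)
  fm <- robust_tic_normalize(fm)
  list(matrix = fm, feature_mz = as.numeric(feature_mz),
       alignment = list(model = align_model, shift_ppm = aligned$shift_ppm),
       calibration = calib_model, axis = axis,
       n_peaks = length(feature_mz), dataset = ds)
}
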