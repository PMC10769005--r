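# Synthetic retina-phantom IMS generator. Emulates a 2D section through outer
# retina: horizontal tissue strata (inner retina / bacillary layer / RPE /
# choroid) with dome-shaped deposit lesions sitting on the RPE, per-stratum
# lipid panels with deposit-exclusive lysolipid markers, 13C isotope
# envelopes, smooth per-pixel mass drift, per-pixel intensity scaling,
# occasional outlier spikes and an additive noise floor. Ground truth (mask,
# drift, scale, marker m/z) is returned so every downstream stage can be
# validated.

#' Configuration of a synthetic IMS phantom
#'
#' @param grid_width,grid_height Grid dimensions in pixels (>= 10).
#' @param strata Named list mapping stratum name to an inclusive 0-based row
#'   band `c(first_row, last_row)`. Bands must be disjoint.
#' @param deposit_stratum Name of the stratum whose top boundary carries the
#'   deposit domes (default `"RPE"`).
#' @param n_deposits Number of dome lesions.
#' @param deposit_radius_px Radius range `c(min, max)` in pixels.
#' @param species_panel Species panel data.frame (see [build_default_panel()]).
#' @param drift_ppm_range Maximum absolute per-pixel mass drift (ppm, >= 0).
#' @param global_error_ppm Systematic mass-error model `c(a, b)`: every peak is
#'   additionally shifted by `a + b * mz` ppm. Default `c(0, 0)`.
#' @param pixel_scale_range Multiplicative per-pixel intensity scale range
#'   (both bounds > 0).
#' @param intensity_cv Lognormal sigma of per-peak intensity variation.
#' @param dropout_rate Probability that an individual species peak is not
#'   detected in a pixel (per-pixel, per-peak detection dropout as in real
#'   centroided MALDI data).
#' @param noise_floor Additive intensity noise s.d. (truncated at zero).
#' @param spike_rate Probability per pixel of one outlier spike peak.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration.
#' @return Object of class `phantom_config`.
#' @export
phantom_config <- function(grid_width = 200L, grid_height = 120L,
                           strata = default_strata(grid_height),
                           deposit_stratum = "RPE",
                           n_deposits = 12L,
                           deposit_radius_px = c(9, 14),
                           species_panel = build_default_panel(),
                           drift_ppm_range = 15,
                           global_error_ppm = c(0, 0),
                           pixel_scale_range = c(0.5, 2),
                           intensity_cv = 0.3,
                           dropout_rate = 0.15,
                           noise_floor = 1,
                           spike_rate = 0.01,
                           seed = 1L) {
  stopifnot(grid_width >= 10, grid_height >= 10,
            drift_ppm_range >= 0, all(pixel_scale_range > 0),
            length(pixel_scale_range) == 2, noise_floor >= 0,
            spike_rate >= 0, spike_rate <= 1, length(global_error_ppm) == 2,
            dropout_rate >= 0, dropout_rate < 1)
  rows_used <- unlist(lapply(strata, function(b) seq(b[1], b[2])))
  if (anyDuplicated(rows_used)) stop_sddmark("strata row bands overlap")
  if (any(rows_used < 0 | rows_used >= grid_height))
    stop_sddmark("strata rows exceed the grid")
  if (!deposit_stratum %in% names(strata))
    stop_sddmark("deposit_stratum '%s' not among strata", deposit_stratum)
  if (max(deposit_radius_px) >= grid_height / 2 ||
      max(deposit_radius_px) >= grid_width / 2)
    stop_sddmark("deposits do not fit on the grid")
  structure(list(grid_width = as.integer(grid_width),
                 grid_height = as.integer(grid_height),
                 strata = strata, deposit_stratum = deposit_stratum,
                 n_deposits = as.integer(n_deposits),
                 deposit_radius_px = deposit_radius_px,
                 species_panel = species_panel,
                 drift_ppm_range = drift_ppm_range,
                 global_error_ppm = global_error_ppm,
                 pixel_scale_range = pixel_scale_range,
                 intensity_cv = intensity_cv, dropout_rate = dropout_rate,
                 noise_floor = noise_floor, spike_rate = spike_rate,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

#' Default tissue strata for a given grid height
#'
#' Four horizontal bands, top to bottom: inner retina, bacillary layer
#' (photoreceptor inner/outer segments), RPE, choroid.
#'
#' @param grid_height Grid height in pixels.
#' @return Named list of inclusive 0-based row bands.
#' @export
default_strata <- function(grid_height = 120L) {
  h <- as.integer(grid_height)
  b1 <- as.integer(floor(h * 1 / 3))      # end of inner retina
  b2 <- as.integer(floor(h * 7 / 12))     # end of bacillary layer
  b3 <- as.integer(floor(h * 17 / 24))    # end of RPE
  list(inner_retina = c(0L, b1 - 1L),
       bacillary    = c(b1, b2 - 1L),
       RPE          = c(b2, b3 - 1L),
       choroid      = c(b3, h - 1L))
}

#' Default species panel of the phantom
#'
#' The panel mirrors the localization classes reported for SDD lipids:
#' deposit-exclusive lysolipids (LysoPC, LysoPE, LysoPA), precursor lipids
#' shared between deposits and the photoreceptor (bacillary) stratum, a
#' sphingomyelin excluded from deposits, ubiquitous calibrant ions, and
#' per-stratum filler species. Each species carries at least two 13C
#' isotopologues.
#'
#' @param n_filler_per_stratum Number of filler species per stratum (default
#'   18), used to make the picked feature space realistically wide.
#' @return data.frame with columns name, class, total_c, total_db, formula,
#'   adduct, base_intensity, compartments (comma-separated), n_isotopes.
#' @export
build_default_panel <- function(n_filler_per_stratum = 18L) {
  sp <- function(name, class, c., db, adduct, base, comp, iso = 3L) {
    data.frame(name = name, class = class, total_c = c., total_db = db,
               adduct = adduct, base_intensity = base,
               compartments = paste(comp, collapse = ","),
               n_isotopes = as.integer(iso), stringsAsFactors = FALSE)
  }
  all_comp <- c("deposit", "inner_retina", "bacillary", "RPE", "choroid")
  panel <- rbind(
    # deposit-exclusive lysolipid markers: monoisotopic + one 13C isotope,
    # the isotope pairing highlighted by the discovery workflow
    sp("LPC(18:3)", "LPC", 18, 3, "+H", 220, "deposit", iso = 2L),
    sp("LPE(18:0)", "LPE", 18, 0, "-H", 260, "deposit", iso = 2L),
    sp("LPA(16:0)", "LPA", 16, 0, "-H", 180, "deposit", iso = 2L),
    # precursors shared between deposit and photoreceptor layer
    sp("PC(32:0)",  "PC", 32, 0, "+H", 240, c("deposit", "bacillary")),
    sp("PE(40:6)",  "PE", 40, 6, "-H", 210, c("deposit", "bacillary", "RPE")),
    sp("PA(32:0)",  "PA", 32, 0, "-H", 170, c("deposit", "bacillary")),
    sp("SM(36:2)",  "SM", 36, 2, "+H", 190, c("deposit", "choroid")),
    # excluded from deposits: present in surrounding layers only
    sp("SM(42:1)",  "SM", 42, 1, "+H", 230, c("bacillary", "RPE", "choroid")),
    sp("PI(34:1)",  "PI", 34, 1, "-H", 160, c("inner_retina", "RPE")),
    # ubiquitous calibrant ions
    sp("PC(32:0)+Na", "PC", 32, 0, "+Na", 150, all_comp),
    sp("PC(34:1)+H",  "PC", 34, 1, "+H",  150, all_comp),
    sp("PC(34:1)+Na", "PC", 34, 1, "+Na", 140, all_comp),
    sp("PI(38:4)-H",  "PI", 38, 4, "-H",  140, all_comp),
    sp("SM(34:1)+H",  "SM", 34, 1, "+H",  130, all_comp),
    # further ubiquitous ions spread over the m/z range so that internal
    # alignment references spanning the axis exist (as in real lipid runs)
    sp("LPA(18:1)-H", "LPA", 18, 1, "-H", 120, all_comp),
    sp("LPC(16:0)+H", "LPC", 16, 0, "+H", 135, all_comp),
    sp("PE(34:1)-H",  "PE", 34, 1, "-H",  125, all_comp),
    sp("SM(42:2)+H",  "SM", 42, 2, "+H",  120, all_comp),
    sp("PI(36:2)-H",  "PI", 36, 2, "-H",  115, all_comp)
  )
  # Deterministic filler species per stratum: vary class and chain length so
  # the picked feature space approaches the width of a real lipid IMS run.
  # Odd-carbon chains keep fillers clear of the even-carbon named species.
  filler_defs <- list(
    inner_retina = list(class = "PI", adduct = "-H", c0 = 31),
    bacillary    = list(class = "PC", adduct = "+H", c0 = 29),
    RPE          = list(class = "PE", adduct = "-H", c0 = 31),
    choroid      = list(class = "SM", adduct = "+H", c0 = 31)
  )
  taken_mz <- expand_species_table(panel)$theoretical_mz
  for (stratum in names(filler_defs)) {
    d <- filler_defs[[stratum]]
    for (i in seq_len(n_filler_per_stratum)) {
      c. <- d$c0 + 2 * ((i - 1) %/% 3)
      db <- (i - 1) %% 3
      # skip fillers that land near an existing peak (e.g. the systematic
      # PC(n:d)[M+H]+ / PE(n+3:d)[M-H]- near-isobars ~1.5 ppm apart)
      mono <- lipid_mz(d$class, c., db, d$adduct)
      cand_mz <- isotope_mz(mono, 0:2)
      if (min(abs(outer(cand_mz, taken_mz, function(a, b)
        (a - b) / b * 1e6))) < 25) next
      nm <- sprintf("%s(%d:%d)@%s", d$class, c., db, stratum)
      panel <- rbind(panel, sp(nm, d$class, c., db, d$adduct,
                               60 + 10 * (i %% 5), stratum, iso = 2L))
      taken_mz <- c(taken_mz, cand_mz[1:2])
    }
  }
  panel$formula <- vapply(seq_len(nrow(panel)), function(i) {
    f <- lipid_class_formula(panel$class[i], panel$total_c[i], panel$total_db[i])
    paste0(names(f), ifelse(f > 1, f, ""), collapse = "")
  }, character(1))
  panel
}

#' Smooth per-pixel mass drift field
#'
#' A low-spatial-frequency scalar field bounded by `+/- drift_ppm_range` ppm:
#' a sum of three long-wavelength cosine modes with random orientation and
#' phase, rescaled so that the maximum absolute value equals 0.95 x the range.
#'
#' @param config A [phantom_config()] (or any list with `grid_width`,
#'   `grid_height`, `drift_ppm_range`, `seed`).
#' @return `grid_height` x `grid_width` matrix of ppm drift values.
#' @export
drift_field <- function(config) {
  w <- config$grid_width; h <- config$grid_height
  r <- config$drift_ppm_range
  if (r == 0) return(matrix(0, nrow = h, ncol = w))
  with_seed(child_seed(config$seed, "drift"), {
    x <- matrix(rep(seq_len(w) - 1, each = h), nrow = h)
    y <- matrix(rep(seq_len(h) - 1, times = w), nrow = h)
    f <- matrix(0, nrow = h, ncol = w)
    for (k in 1:3) {
      fx <- stats::runif(1, 0.2, 1.2) / w
      fy <- stats::runif(1, 0.2, 1.2) / h
      ph <- stats::runif(1, 0, 2 * pi)
      amp <- stats::runif(1, 0.4, 1)
      f <- f + amp * cos(2 * pi * (fx * x + fy * y) + ph)
    }
    f * (0.95 * r / max(abs(f)))
  })
}

# Place deposit domes: discs centred on the top boundary row of the deposit
# stratum, horizontal centres spread to limit overlap. Returns list(mask,
# centers, radii).
place_deposits <- function(config) {
  w <- config$grid_width; h <- config$grid_height
  n <- config$n_deposits
  band <- config$strata[[config$deposit_stratum]]
  boundary_row <- band[1]
  rr <- config$deposit_radius_px
  if (boundary_row - max(rr) < 0 || boundary_row + max(rr) >= h)
    stop_sddmark("deposits of radius %g do not fit on stratum '%s'",
                 max(rr), config$deposit_stratum)
  mask <- matrix(FALSE, nrow = h, ncol = w)
  if (n == 0) return(list(mask = mask, height = mask * 0,
                          centers = cbind(x = integer(), y = integer()),
                          radii = numeric()))
  with_seed(child_seed(config$seed, "deposits"), {
    radii <- stats::runif(n, rr[1], rr[2])
    # jittered stratified centres along x keep lesions mostly non-overlapping
    slots <- (seq_len(n) - 0.5) / n * w
    cx <- pmin(pmax(slots + stats::runif(n, -0.25, 0.25) * w / n, max(rr)),
               w - 1 - max(rr))
    cy <- rep(boundary_row, n)
    xg <- matrix(rep(seq_len(w) - 1, each = h), nrow = h)
    yg <- matrix(rep(seq_len(h) - 1, times = w), nrow = h)
    # hemispherical dome profile: relative deposit thickness at each pixel,
    # 1 at the lesion centre, 0 at the rim (partial-volume weight)
    height <- matrix(0, nrow = h, ncol = w)
    for (i in seq_len(n)) {
      d2 <- ((xg - cx[i])^2 + (yg - cy[i])^2) / radii[i]^2
      height <- pmax(height, sqrt(pmax(0, 1 - d2)))
      mask <- mask | (d2 <= 1)
    }
    list(mask = mask, height = height, centers = cbind(x = cx, y = cy),
         radii = radii)
  })
}

#' Generate a synthetic IMS phantom with ground truth
#'
#' Produces one centroid spectrum per grid pixel. Each pixel emits the
#' theoretical adduct/isotopologue m/z values of the species present in its
#' compartment(s) (stratum, plus "deposit" inside a lesion); intensities are
#' `base_intensity * pixel_scale * lognormal(intensity_cv) * isotope_ratio`
#' plus truncated Gaussian noise; m/z values are perturbed multiplicatively by
#' the smooth per-pixel drift and the global systematic error. Inside a
#' lesion the dome displaces stratum tissue in proportion to its local
#' thickness (hemispherical profile): deposit-species intensities scale with
#' the dome height and displaced stratum-species intensities with its
#' complement, so lesion edges carry mixed signal as in real sections.
#'
#' @param config A [phantom_config()].
#' @return list with elements `dataset` (an `ims_dataset`) and `truth`
#'   (deposit_mask, stratum_map, true_marker_mz, marker_names, drift_ppm,
#'   scale, centers, radii, panel_mz).
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  w <- config$grid_width; h <- config$grid_height
  panel <- expand_species_table(config$species_panel)
  # per-isotopologue relative abundance: binomial 13C model from carbon count
  n_c <- vapply(panel$formula, function(f) parse_formula(f)[["C"]], numeric(1))
  p13 <- 0.0107
  panel$abundance <- stats::dbinom(panel$n13c, n_c, p13) / stats::dbinom(0, n_c, p13)
  base_int <- config$species_panel$base_intensity[match(panel$name, config$species_panel$name)]
  comp_str <- config$species_panel$compartments[match(panel$name, config$species_panel$name)]
  panel_comp <- strsplit(comp_str, ",")

  compartments <- c("deposit", names(config$strata))
  peaks_by_comp <- lapply(compartments, function(cc) {
    keep <- vapply(panel_comp, function(x) cc %in% x, logical(1))
    idx <- which(keep)
    idx[order(panel$theoretical_mz[idx])]
  })
  names(peaks_by_comp) <- compartments
  ubiquitous <- vapply(panel_comp, function(x) length(x) >= length(compartments) - 1 &&
                         all(names(config$strata) %in% x), logical(1))

  dep <- place_deposits(config)
  stratum_map <- matrix(NA_character_, nrow = h, ncol = w)
  for (s in names(config$strata)) {
    b <- config$strata[[s]]
    stratum_map[(b[1]:b[2]) + 1L, ] <- s
  }
  drift <- drift_field(config)
  ge <- config$global_error_ppm

  with_seed(child_seed(config$seed, "intensity"), {
    n_pix <- w * h
    scale <- matrix(exp(stats::runif(n_pix, log(config$pixel_scale_range[1]),
                                     log(config$pixel_scale_range[2]))),
                    nrow = h, ncol = w)
    spike_here <- matrix(stats::runif(n_pix) < config$spike_rate, nrow = h, ncol = w)
    mz_list <- vector("list", n_pix)
    int_list <- vector("list", n_pix)
    coords <- matrix(0L, nrow = n_pix, ncol = 2,
                     dimnames = list(NULL, c("x", "y")))
    k <- 0L
    for (y in 0:(h - 1)) {
      for (x in 0:(w - 1)) {
        k <- k + 1L
        coords[k, ] <- c(x, y)
        s <- stratum_map[y + 1L, x + 1L]
        s_idx <- if (!is.na(s)) peaks_by_comp[[s]] else integer()
        hgt <- dep$height[y + 1L, x + 1L]
        if (dep$mask[y + 1L, x + 1L] && hgt > 0) {
          # partial-volume mixing: the dome displaces stratum tissue in
          # proportion to its local thickness
          d_idx <- peaks_by_comp[["deposit"]]
          idx <- sort(union(d_idx, s_idx))
          wt <- pmin(1, hgt * (idx %in% d_idx) + (1 - hgt) * (idx %in% s_idx))
        } else {
          idx <- s_idx
          wt <- rep(1, length(idx))
        }
        if (length(idx) && config$dropout_rate > 0) {
          keep <- stats::runif(length(idx)) >= config$dropout_rate
          idx <- idx[keep]
          wt <- wt[keep]
        }
        if (length(idx)) {
          mu <- base_int[idx] * panel$abundance[idx] * wt * scale[y + 1L, x + 1L]
          ints <- mu * stats::rlnorm(length(idx),
                                     -config$intensity_cv^2 / 2,
                                     config$intensity_cv)
          if (config$noise_floor > 0)
            ints <- pmax(ints + stats::rnorm(length(idx), 0, config$noise_floor), 0)
          mzs <- panel$theoretical_mz[idx]
        } else {
          ints <- numeric(); mzs <- numeric()
        }
        if (spike_here[y + 1L, x + 1L]) {
          smz <- stats::runif(1, 320, 1900)
          sint <- (if (length(ints)) max(ints) else 100) * stats::runif(1, 50, 200)
          pos <- findInterval(smz, mzs)
          mzs <- append(mzs, smz, after = pos)
          ints <- append(ints, sint, after = pos)
        }
        d_tot <- (drift[y + 1L, x + 1L] + ge[1] + ge[2] * mzs) * 1e-6
        mz_list[[k]] <- mzs * (1 + d_tot)
        int_list[[k]] <- ints
      }
    }
  })

  marker_only <- vapply(panel_comp, function(x) identical(x, "deposit"), logical(1))
  dataset <- new_ims_dataset(mz = mz_list, intensity = int_list, coords = coords,
                             polarity = "positive",
                             mz_range = c(300, 2000),
                             grid_shape = c(w, h),
                             provenance = list(source = "sddmark phantom",
                                               seed = config$seed))
  truth <- list(deposit_mask = dep$mask, stratum_map = stratum_map,
                true_marker_mz = panel$theoretical_mz[marker_only],
                marker_names = paste0(panel$name[marker_only], "+", panel$n13c[marker_only]),
                excluded_mz = panel$theoretical_mz[
                  vapply(panel_comp, function(x) !"deposit" %in% x, logical(1)) &
                    panel$name %in% c("SM(42:1)")],
                drift_ppm = drift, scale = scale,
                partial_volume = dep$height,
                centers = dep$centers, radii = dep$radii,
                panel_mz = panel$theoretical_mz)
  list(dataset = dataset, truth = truth)
}
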