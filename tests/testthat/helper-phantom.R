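# Shared fixtures: small phantoms keep unit tests fast; the full-size default
# configuration is exercised only in the acceptance tests.

small_phantom_config <- function(seed = 1, ...) {
  args <- list(grid_width = 60L, grid_height = 48L,
               strata = default_strata(48L),
               n_deposits = 4L, deposit_radius_px = c(4, 6),
               species_panel = build_default_panel(n_filler_per_stratum = 6L),
               drift_ppm_range = 10, noise_floor = 0.5, spike_rate = 0.005,
               seed = seed)
  args[names(list(...))] <- list(...)
  do.call(phantom_config, args)
}

# Noise-free configuration: peaks at exact theoretical positions.
clean_phantom_config <- function(seed = 1, ...) {
  small_phantom_config(seed = seed, drift_ppm_range = 0, noise_floor = 0,
                       intensity_cv = 0, dropout_rate = 0, spike_rate = 0, ...)
}

# A tiny hand-built dataset: `peaks` is a list of matrices cbind(mz, int),
# one per pixel, laid out on a 1-row grid.
toy_dataset <- function(peaks, polarity = "positive", mz_range = c(300, 2000)) {
  new_ims_dataset(mz = lapply(peaks, function(p) p[, 1]),
                  intensity = lapply(peaks, function(p) p[, 2]),
                  coords = cbind(x = seq_along(peaks) - 1L, y = 0L),
                  polarity = polarity, mz_range = mz_range,
                  grid_shape = c(length(peaks), 1L))
}

expect_ppm_equal <- function(observed, expected, tol_ppm = 1) {
  expect_true(all(abs((observed - expected) / expected * 1e6) <= tol_ppm),
              label = sprintf("%.6f within %g ppm of %.6f",
                              observed[1], tol_ppm, expected[1]))
}
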