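# Internal helpers shared across the pipeline.

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a stage-specific child seed from a master seed; stays below 2^31.
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  (as.double(seed) * 48271 + sum(utf8ToInt(stage)) * 9973) %% 2147483587 + 1
}

ppm_error <- function(observed, theoretical) {
  (observed - theoretical) / theoretical * 1e6
}

ppm_window <- function(mz, tol_ppm) {
  c(mz * (1 - tol_ppm * 1e-6), mz * (1 + tol_ppm * 1e-6))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_sddmark <- function(...) stop(sprintf(...), call. = FALSE)

# Linear (row-major over the grid, x fastest) pixel index <-> coordinates.
# Coordinates are 0-based, x = column, y = row.
pixel_linear_index <- function(coords, grid_shape) {
  coords[, 2L] * grid_shape[1L] + coords[, 1L] + 1L
}

linear_to_coords <- function(idx, grid_shape) {
  idx0 <- idx - 1L
  cbind(x = idx0 %% grid_shape[1L], y = idx0 %/% grid_shape[1L])
}
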