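# End-to-end orchestration: simulate -> preprocess -> label -> train ->
# interpret -> annotate, driven by one nested configuration with a single
# master seed. Every stage logs the quantities a user compares against an
# acquisition report (picked-peak counts, class sizes, residual ppm).

#' Default pipeline configuration
#'
#' Nested configuration of all stages with the workflow's standard constants
#' as named defaults: 6 alignment peaks at 50% minimum occupancy, >= 4
#' calibrants, 1.5 ppm common-axis spacing, 7 ppm feature windows, 67/33
#' stratified split, top-20 shortlist.
#'
#' @param seed Master seed (default 1).
#' @param out_dir Optional output directory; `NULL` keeps everything
#'   in memory.
#' @return Nested list of class `run_config`.
#' @export
default_run_config <- function(seed = 1, out_dir = NULL) {
  structure(list(
    seed = seed,
    out_dir = out_dir,
    phantom = list(grid_width = 200L, grid_height = 120L, n_deposits = 12L,
                   deposit_radius_px = c(9, 14), drift_ppm_range = 15,
                   global_error_ppm = c(0, 0), pixel_scale_range = c(0.5, 2),
                   intensity_cv = 0.3, dropout_rate = 0.15,
                   noise_floor = 1, spike_rate = 0.01),
    preprocess = list(axis_ppm = 1.5, n_align_peaks = 6L, min_fraction = 0.5,
                      tol_ppm = 7, snr_threshold = 3),
    labeling = list(rank = 8L, component = NULL, threshold_quantile = NULL),
    classify = list(train_fraction = 0.67, nrounds = 200L, max_depth = 4L,
                    eta = 0.1, colsample_bytree = 0.5),
    interpret = list(top_n = 20L),
    annotate = list(tol_ppm = 10)
  ), class = "run_config")
}

.config_keys <- c("seed", "out_dir", "input", "phantom", "preprocess",
                  "labeling", "classify", "interpret", "annotate")

#' Read a pipeline configuration from YAML
#'
#' Unknown top-level keys are rejected; known sections are merged over the
#' defaults of [default_run_config()].
#'
#' @param path YAML file path.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  bad <- setdiff(names(user), .config_keys)
  if (length(bad))
    stop_sddmark("unknown configuration key(s): %s", paste(bad, collapse = ", "))
  cfg <- default_run_config(seed = user$seed %||% 1, out_dir = user$out_dir)
  for (sec in intersect(names(user), setdiff(.config_keys, c("seed", "out_dir")))) {
    if (sec == "input") { cfg$input <- user$input; next }
    bad <- setdiff(names(user[[sec]]), names(cfg[[sec]]))
    if (length(bad))
      stop_sddmark("unknown key(s) in section '%s': %s", sec,
                   paste(bad, collapse = ", "))
    cfg[[sec]][names(user[[sec]])] <- user[[sec]]
  }
  cfg
}

#' Run the full marker-discovery pipeline
#'
#' Executes simulate (or load), preprocess, label, train, interpret and
#' annotate in order, and returns a run report. Re-running with the same
#' configuration and seed reproduces the metrics and shortlist exactly
#' (all stages are single-threaded and seeded).
#'
#' @param config A `run_config` (see [default_run_config()],
#'   [read_run_config()]).
#' @param dataset Optional pre-built `ims_dataset`; if `NULL`, a phantom is
#'   generated from `config$phantom` (or `config$input` is read as imzML).
#' @param truth Optional phantom ground truth (carried into the report).
#' @param verbose Log per-stage progress and counts (default TRUE).
#' @return Object of class `sdd_run_report`.
#' @export
run_pipeline <- function(config = default_run_config(), dataset = NULL,
                         truth = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  stage <- "simulate"
  report <- list(seed = config$seed, config = config,
                 version = as.character(utils::packageVersion("sddmark")),
                 stages = list())
  result <- tryCatch({
    # --- simulate / load -----------------------------------------------------
    if (is.null(dataset)) {
      if (!is.null(config$input)) {
        say("[load] reading %s", config$input)
        dataset <- read_imzml(config$input)
      } else {
        say("[simulate] generating phantom (%dx%d, %d deposits)",
            config$phantom$grid_width, config$phantom$grid_height,
            config$phantom$n_deposits)
        pc <- do.call(phantom_config, c(config$phantom, list(seed = config$seed)))
        ph <- generate_phantom(pc)
        dataset <- ph$dataset
        truth <- ph$truth
      }
    }
    report$stages$simulate <- list(n_pixels = length(dataset),
                                   grid_shape = dataset$grid_shape)

    # --- preprocess ----------------------------------------------------------
    stage <- "preprocess"
    calibrants <- calibrant_table()$theoretical_mz
    pp <- do.call(preprocess_dataset,
                  c(list(dataset = dataset, calibrants = calibrants),
                    config$preprocess))
    say("[preprocess] %d peaks picked; median |residual| %.3f ppm",
        pp$n_peaks,
        if (!is.null(pp$calibration)) pp$calibration$median_abs_residual_ppm else NA)
    report$stages$preprocess <- list(
      n_peaks = pp$n_peaks,
      alignment_shift_ppm_range = range(pp$alignment$shift_ppm),
      calibration = if (!is.null(pp$calibration))
        list(coefficients = pp$calibration$coefficients,
             median_abs_residual_ppm = pp$calibration$median_abs_residual_ppm))

    # --- label ---------------------------------------------------------------
    stage <- "label"
    nmf <- nmf_patterns(pp$matrix, rank = config$labeling$rank, seed = config$seed)
    mask <- mask_from_pattern(nmf, component = config$labeling$component,
                              threshold_quantile = config$labeling$threshold_quantile)
    labels <- balance_labels(mask, seed = config$seed)
    say("[label] component %d -> %d SDD pixels, %d background sampled",
        attr(mask, "component"), nrow(labels$positive), nrow(labels$negative))
    report$stages$label <- list(component = attr(mask, "component"),
                                n_positive = nrow(labels$positive),
                                n_negative = nrow(labels$negative),
                                balance_ratio = labels$balance_ratio)

    # --- train ---------------------------------------------------------------
    stage <- "train"
    model <- do.call(sdd_classifier,
                     c(list(matrix = pp$matrix, labels = labels,
                            seed = config$seed), config$classify))
    say("[train] held-out balanced accuracy %.4f, F1 %.4f",
        model$metrics$balanced_accuracy, model$metrics$f1)
    report$stages$train <- list(metrics = unclass(model$metrics)[
      c("balanced_accuracy", "precision", "recall", "f1")])

    # --- interpret -----------------------------------------------------------
    stage <- "interpret"
    shap <- shap_values(model, pp$matrix)

    # --- annotate ------------------------------------------------------------
    stage <- "annotate"
    species <- expand_species_table(build_default_panel())
    annotations <- annotate_peaks(pp$feature_mz, species,
                                  tol_ppm = config$annotate$tol_ppm)
    shortlist <- marker_shortlist(shap, annotations,
                                  top_n = config$interpret$top_n)
    say("[interpret] top feature m/z %.4f (%s)",
        shortlist$feature_mz[1], shortlist$direction[1])

    list(dataset = dataset, truth = truth, preprocess = pp, nmf = nmf,
         mask = mask, labels = labels, model = model, shap = shap,
         annotations = annotations, shortlist = shortlist)
  }, error = function(e) {
    stop_sddmark("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })

  report$metrics <- result$model$metrics
  report$shortlist <- result$shortlist
  report$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  report$result <- result

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    manifest <- write_run_outputs(report, config$out_dir)
    report$manifest <- manifest
  }
  class(report) <- "sdd_run_report"
  report
}

write_run_outputs <- function(report, out_dir) {
  res <- report$result
  paths <- c(
    shortlist = file.path(out_dir, "shortlist.csv"),
    report = file.path(out_dir, "report.json"),
    mask = file.path(out_dir, "label_mask.csv"),
    features = file.path(out_dir, "feature_mz.csv")
  )
  utils::write.csv(as.data.frame(res$shortlist), paths[["shortlist"]],
                   row.names = FALSE)
  write_label_mask(res$mask, paths[["mask"]])
  utils::write.csv(data.frame(feature_mz = res$preprocess$feature_mz),
                   paths[["features"]], row.names = FALSE)
  json <- list(seed = report$seed, version = report$version,
               stages = report$stages,
               metrics = unclass(report$metrics)[
                 c("balanced_accuracy", "precision", "recall", "f1")],
               shortlist = as.data.frame(report$shortlist))
  jsonlite::write_json(json, paths[["report"]], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths
}

#' @export
print.sdd_run_report <- function(x, ...) {
  cat(sprintf("<sdd_run_report> seed %s, %.1f s\n", x$seed, x$elapsed_s))
  cat(sprintf("  %d peaks | %d+%d labels | ", x$stages$preprocess$n_peaks,
              x$stages$label$n_positive, x$stages$label$n_negative))
  print(x$metrics)
  print(x$shortlist)
  invisible(x)
}
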