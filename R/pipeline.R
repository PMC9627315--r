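# End-to-end pipeline: synthetic generation or ingest, preprocessing,
# features, ERD/S maps, classification, and neighbor analysis, wired
# together with a single configuration object and a run manifest.

#' Pipeline configuration
#'
#' Defaults reproduce the study settings: resample to 200 Hz, 60 Hz notch
#' cascade, bad-channel z threshold 6 with 10% bad-run fraction, mu 8-12 Hz
#' and beta 13-25 Hz band power in 0.25 s segments smoothed over 0.75 s,
#' 25 s power-shift compensation, epochs -0.5..7 s, ERD/S reference
#' -0.5..0 s, 2.5th-percentile focal selection, 0-5 s classification
#' window with 10x10-fold CV and 100 permutations.
#'
#' @param preset synthetic preset name (see [synthetic_preset()]) or `NULL`
#'   when `runs`/`montage` are supplied directly.
#' @param seed integer base seed for generation and inference.
#' @param fs_out,notch_hz,bad_z,bad_run_frac preprocessing parameters.
#' @param bands named list of band corner frequencies.
#' @param segment_s,smooth_s,compensation_s feature parameters.
#' @param epoch_pre_s,epoch_post_s epoch window.
#' @param reference_window_s ERD/S reference window.
#' @param focal_window_s,focal_percentile focal-selection parameters.
#' @param task_window_s classified time window.
#' @param cv_iterations,cv_folds,n_permutations classification parameters.
#' @return list of class `uhd_config`.
#' @export
pipeline_config <- function(preset = "demo", seed = 1, fs_out = 200,
                            notch_hz = 60, bad_z = 6, bad_run_frac = 0.1,
                            bands = list(mu = c(8, 12), beta = c(13, 25)),
                            segment_s = 0.25, smooth_s = 0.75,
                            compensation_s = 25, epoch_pre_s = 0.5,
                            epoch_post_s = 7,
                            reference_window_s = c(-0.5, 0),
                            focal_window_s = c(1, 2),
                            focal_percentile = 2.5,
                            task_window_s = c(0, 5), cv_iterations = 10,
                            cv_folds = 10, n_permutations = 100) {
  cfg <- as.list(environment())
  class(cfg) <- "uhd_config"
  cfg
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config `uhd_config`.
#' @param path file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns
#'   a `uhd_config` (unknown keys are rejected).
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "uhd_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  if (!is.null(vals$bands))
    vals$bands <- lapply(vals$bands, as.numeric)
  do.call(pipeline_config, vals)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes synthesis (or ingest) -> preprocessing -> band-power features
#' -> epoching -> per-finger ERD/S with focal selection -> pairwise
#' classification -> neighbor correlation analysis, and returns all stage
#' outputs plus a machine-readable manifest. Deterministic given the
#' configuration seed.
#'
#' @param config `uhd_config`.
#' @param runs optional list of `uhd_recording` (one per run) to analyse
#'   instead of synthesizing; requires `montage`.
#' @param montage montage matching `runs`.
#' @return list of class `uhd_pipeline` with elements `montage`, `report`,
#'   `kept_channels`, `epochs` (per band and combined), `erds` (per
#'   finger, beta band), `focal`, `classification` (table + results),
#'   `neighbors`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), runs = NULL,
                         montage = NULL) {
  stopifnot(inherits(config, "uhd_config"))
  cfg <- config

  if (is.null(runs)) {
    study <- stage("synthetic", {
      synthesize_study(synthetic_preset(cfg$preset), seed = cfg$seed)
    })
    runs <- study$runs
    montage <- study$montage
  } else if (is.null(montage)) {
    stop("[stage input] 'montage' is required when supplying recordings")
  }

  pre <- stage("preprocess", {
    preprocess_study(runs, fs_out = cfg$fs_out, notch_hz = cfg$notch_hz,
                     threshold_z = cfg$bad_z,
                     run_fraction = cfg$bad_run_frac)
  })
  kept <- pre$kept_channels
  mont_kept <- subset_montage(montage, kept, recompute_edge = FALSE)

  band_epochs <- stage("features", {
    if (is.null(names(cfg$bands)) || any(names(cfg$bands) == ""))
      stop("bands must be a named list")
    lapply(cfg$bands, function(bd) {
      if (!is.numeric(bd) || length(bd) != 2L)
        stop("unknown band specification")
      per_run <- lapply(pre$runs, function(r) {
        f <- band_power(r, bd, segment_s = cfg$segment_s,
                        smooth_s = cfg$smooth_s)
        f <- power_shift_compensation(f, cfg$compensation_s)
        epoch_features(f, pre_s = cfg$epoch_pre_s,
                       post_s = cfg$epoch_post_s)
      })
      bind_epochs(per_run)
    })
  })
  epochs <- combine_bands(band_epochs)

  erds_maps <- stage("erds", {
    fingers <- sort(unique(attr(epochs, "labels")))
    maps <- lapply(fingers, function(f)
      compute_erds(band_epochs[[length(band_epochs)]],
                   reference_window_s = cfg$reference_window_s,
                   finger = f))
    names(maps) <- fingers
    maps
  })
  focal <- stage("erds", {
    focal_selection(erds_maps, window_s = cfg$focal_window_s,
                    percentile = cfg$focal_percentile)
  })

  roi_mask <- rep(mont_kept$roi, length(cfg$bands))
  classification <- stage("classify", {
    all_pairwise_cv(epochs, roi = roi_mask,
                    time_window_s = cfg$task_window_s,
                    n_iterations = cfg$cv_iterations,
                    k_folds = cfg$cv_folds, seed_base = 1,
                    n_permutations = cfg$n_permutations,
                    perm_seed = cfg$seed)
  })

  nb <- stage("neighbors", {
    graph <- four_nearest_neighbors(mont_kept)
    neighbor_correlations(pre$runs[[1]], graph)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("uhdfinger")),
    parameters = unclass(cfg),
    n_runs_in = length(runs),
    n_runs_kept = length(pre$kept_runs),
    n_channels_kept = length(kept),
    bad_channels = which(pre$report$bad_channels),
    bad_runs = which(pre$report$bad_runs))

  structure(list(montage = mont_kept, report = pre$report,
                 kept_channels = kept, band_epochs = band_epochs,
                 epochs = epochs, erds = erds_maps, focal = focal,
                 classification = classification, neighbors = nb,
                 manifest = manifest),
            class = "uhd_pipeline")
}

#' @export
print.uhd_pipeline <- function(x, ...) {
  cat("uHD finger-decoding pipeline result\n")
  print(x$montage)
  print(x$report)
  cat(sprintf("  %d epochs, %d classification pairs\n",
              dim(x$epochs)[1], nrow(x$classification$table)))
  invisible(x)
}

#' Save pipeline outputs to a directory
#'
#' Writes the classification table, neighbor-pair statistics, focal
#' selections and the JSON run manifest as plain files.
#'
#' @param result `uhd_pipeline`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_results <- function(result, dir) {
  stopifnot(inherits(result, "uhd_pipeline"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$classification$table,
                   file.path(dir, "classification.csv"), row.names = FALSE)
  utils::write.csv(result$neighbors$pairs,
                   file.path(dir, "neighbor_pairs.csv"), row.names = FALSE)
  utils::write.csv(result$neighbors$summary,
                   file.path(dir, "neighbor_summary.csv"),
                   row.names = FALSE)
  focal <- result$focal
  utils::write.csv(
    data.frame(finger = rep(names(focal), lengths(focal)),
               electrode = unlist(focal)),
    file.path(dir, "focal_electrodes.csv"), row.names = FALSE)
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
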