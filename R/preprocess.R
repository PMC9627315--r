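# Preprocessing: polyphase resampling, Butterworth notch-filter cascade,
# statistical bad-channel / bad-run identification, and common average
# referencing. Notch and band-pass filters are applied forward-only
# (causal); only the bad-channel statistics are computed offline.

#' Resample a recording
#'
#' Anti-aliased polyphase resampling (zero-stuffing by p, FIR low-pass,
#' zero-phase application with reflection padding, decimation by q). Event
#' onsets are expressed in seconds and therefore preserved.
#'
#' @param rec `uhd_recording`.
#' @param fs_out target sampling rate in Hz; must be below `rec$fs` and in
#'   rational ratio with it.
#' @return resampled `uhd_recording`.
#' @export
resample_recording <- function(rec, fs_out) {
  stopifnot(inherits(rec, "uhd_recording"))
  check_scalar(fs_out, "fs_out", lower = 1e-9)
  if (fs_out >= rec$fs)
    stop("'fs_out' must be smaller than the input sampling rate")
  frac <- fs_out / rec$fs
  # small-denominator rational approximation of the rate ratio
  pq <- NULL
  for (q in 1:1000) {
    p <- frac * q
    if (abs(p - round(p)) < 1e-9) { pq <- c(round(p), q); break }
  }
  if (is.null(pq)) stop("fs_out / fs must be a rational ratio")
  n_out <- round(ncol(rec$data) * frac)
  out <- matrix(0, nrow(rec$data), n_out)
  for (i in seq_len(nrow(rec$data))) {
    y <- resample_signal(rec$data[i, ], pq[1], pq[2])
    out[i, ] <- y[seq_len(n_out)]
  }
  recording(out, fs_out, rec$labels, rec$events)
}

#' Notch-filter cascade at a base frequency and its harmonics
#'
#' Applies 4th-order Butterworth band-stop filters (stop band +/- 2 Hz
#' around each notch center) causally, at `base_hz` and every harmonic
#' strictly below Nyquist.
#'
#' @param rec `uhd_recording`.
#' @param base_hz line frequency (default 60).
#' @param width_hz full stop-band width per notch (default 4).
#' @return filtered `uhd_recording`.
#' @export
notch_cascade <- function(rec, base_hz = 60, width_hz = 4) {
  stopifnot(inherits(rec, "uhd_recording"))
  ny <- rec$fs / 2
  if (base_hz >= ny) stop("'base_hz' must be below Nyquist (", ny, " Hz)")
  freqs <- base_hz * seq_len(floor(ny / base_hz))
  freqs <- freqs[freqs + width_hz / 2 < ny]  # stop band must fit
  x <- rec$data
  for (f0 in freqs) {
    bf <- signal::butter(4, c(f0 - width_hz / 2, f0 + width_hz / 2) / ny,
                         type = "stop")
    x <- filter_rows(bf$b, bf$a, x)
  }
  recording(x, rec$fs, rec$labels, rec$events)
}

#' Identify bad channels and bad runs
#'
#' Per run: common average reference, band-pass (4th-order Butterworth,
#' causal), restriction to task-period samples, per-channel mean power
#' (mean-subtracted, squared, time-averaged), log10 transform, and z-scoring
#' across channels. Channels with z above `threshold_z` in any retained run
#' are bad (cross-run disjunction); runs in which more than `run_fraction`
#' of channels are bad are removed before the disjunction. The input data
#' are not modified -- only a report is returned.
#'
#' @param runs list of `uhd_recording` (one per run), already notch
#'   filtered.
#' @param band band-pass corner frequencies in Hz (default 8-25).
#' @param threshold_z z-score threshold for a bad channel (default 6).
#' @param run_fraction fraction of bad channels above which a run is
#'   removed (default 0.1).
#' @param task_types trial types counted as task; defaults to every type
#'   except `"rest"` and `"baseline"`.
#' @return object of class `uhd_bad_report`: list with `z_scores`
#'   (channels x runs), `bad_channels` (logical), `bad_runs` (logical),
#'   `threshold_z`, `run_fraction`.
#' @export
identify_bad_channels <- function(runs, band = c(8, 25), threshold_z = 6,
                                  run_fraction = 0.1, task_types = NULL) {
  stopifnot(length(runs) >= 1L, all(vapply(runs, inherits, TRUE,
                                           "uhd_recording")))
  nch <- nrow(runs[[1]]$data)
  if (nch < 2L) stop("at least 2 channels required")
  z <- matrix(NA_real_, nch, length(runs))
  for (r in seq_along(runs)) {
    rec <- runs[[r]]
    ev <- rec$events
    if (is.null(task_types))
      tt <- setdiff(unique(ev$trial_type), c("rest", "baseline"))
    else tt <- task_types
    task <- ev[ev$trial_type %in% tt, , drop = FALSE]
    if (nrow(task) == 0L) stop("run ", r, " has no task events")
    x <- rec$data
    x <- sweep(x, 2, colMeans(x))                 # CAR
    x <- bandpass_rows(x, band, rec$fs)
    keep <- logical(ncol(x))
    for (k in seq_len(nrow(task))) {
      i0 <- floor(task$onset[k] * rec$fs) + 1L
      i1 <- min(ncol(x), ceiling((task$onset[k] + task$duration[k]) * rec$fs))
      keep[i0:i1] <- TRUE
    }
    x <- x[, keep, drop = FALSE]
    pow <- rowMeans((x - rowMeans(x))^2)
    lp <- log10(pow)
    z[, r] <- (lp - mean(lp)) / stats::sd(lp)
  }
  bad_by_run <- z > threshold_z
  bad_runs <- colMeans(bad_by_run) > run_fraction
  retained <- which(!bad_runs)
  if (length(retained) == 0L)
    stop("all runs flagged bad; degenerate data")
  bad_channels <- apply(bad_by_run[, retained, drop = FALSE], 1, any)
  if (all(bad_channels))
    stop("all channels flagged bad; degenerate data")
  structure(list(z_scores = z, bad_channels = bad_channels,
                 bad_runs = bad_runs, threshold_z = threshold_z,
                 run_fraction = run_fraction),
            class = "uhd_bad_report")
}

#' @export
print.uhd_bad_report <- function(x, ...) {
  cat(sprintf("bad-channel report: %d/%d channels bad (z > %g), %d/%d runs removed\n",
              sum(x$bad_channels), length(x$bad_channels), x$threshold_z,
              sum(x$bad_runs), length(x$bad_runs)))
  invisible(x)
}

#' Common average referencing
#'
#' Subtracts, at each sample, the mean over included channels; excluded
#' (bad) channels are dropped from the output.
#'
#' @param rec `uhd_recording`.
#' @param exclude logical mask (or integer indices) of channels to drop.
#' @return re-referenced `uhd_recording` containing only included channels.
#' @export
apply_car <- function(rec, exclude = NULL) {
  stopifnot(inherits(rec, "uhd_recording"))
  nch <- nrow(rec$data)
  drop_idx <- if (is.null(exclude)) integer(0)
  else if (is.logical(exclude)) which(exclude)
  else as.integer(exclude)
  keep <- setdiff(seq_len(nch), drop_idx)
  if (length(keep) < 2L) stop("at least 2 included channels required")
  x <- rec$data[keep, , drop = FALSE]
  x <- sweep(x, 2, colMeans(x))
  recording(x, rec$fs, rec$labels[keep], rec$events)
}

#' Run the full preprocessing chain on a study
#'
#' Resample, notch cascade, bad-channel/run identification, removal, and
#' common average referencing, per run.
#'
#' @param runs list of `uhd_recording`.
#' @param fs_out target sampling rate (Hz); `NULL` to skip resampling.
#' @param notch_hz notch base frequency; `NULL` to skip.
#' @param threshold_z,run_fraction bad-channel parameters.
#' @return list with `runs` (preprocessed retained runs), `report`
#'   (`uhd_bad_report`), `kept_channels` (indices into the input channels),
#'   `kept_runs`.
#' @export
preprocess_study <- function(runs, fs_out = 200, notch_hz = 60,
                             threshold_z = 6, run_fraction = 0.1) {
  proc <- lapply(runs, function(r) {
    if (!is.null(fs_out) && fs_out < r$fs) r <- resample_recording(r, fs_out)
    if (!is.null(notch_hz)) r <- notch_cascade(r, notch_hz)
    r
  })
  report <- identify_bad_channels(proc, threshold_z = threshold_z,
                                  run_fraction = run_fraction)
  kept_runs <- which(!report$bad_runs)
  kept_channels <- which(!report$bad_channels)
  out <- lapply(proc[kept_runs], apply_car, exclude = report$bad_channels)
  list(runs = out, report = report, kept_channels = kept_channels,
       kept_runs = kept_runs)
}
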