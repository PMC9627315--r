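# Band-power feature extraction: causal band-pass, squaring, segment
# averaging, centered moving-average smoothing, log transform, trailing
# power-shift compensation, and epoching.

#' Log band-power features
#'
#' Band-pass filters each channel (4th-order Butterworth, causal), squares
#' the samples, averages power within non-overlapping segments, applies a
#' centered moving average (shrinking windows at the edges), and takes
#' log10.
#'
#' @param rec `uhd_recording` (preprocessed).
#' @param band band corner frequencies in Hz, e.g. `c(8, 12)` for mu.
#' @param segment_s segment length in s (default 0.25; the feature rate is
#'   `1/segment_s`).
#' @param smooth_s centered moving-average window in s (default 0.75; must
#'   be an odd multiple of `segment_s`).
#' @return object of class `uhd_features`: list with `values` (channels x
#'   feature samples, log10 band power), `feature_fs`, `band`, `segment_s`,
#'   `labels`, `events`, `compensated`.
#' @export
band_power <- function(rec, band, segment_s = 0.25, smooth_s = 0.75) {
  stopifnot(inherits(rec, "uhd_recording"))
  ny <- rec$fs / 2
  if (!(band[1] > 0 && band[1] < band[2] && band[2] < ny))
    stop("band must lie strictly inside (0, Nyquist)")
  spb <- rec$fs * segment_s
  if (abs(spb - round(spb)) > 1e-9)
    stop("segment_s must be an integer number of samples at fs")
  spb <- as.integer(round(spb))
  width <- smooth_s / segment_s
  if (abs(width - round(width)) > 1e-9 || round(width) %% 2L != 1L)
    stop("smooth_s must be an odd multiple of segment_s")
  width <- as.integer(round(width))

  x <- bandpass_rows(rec$data, band, rec$fs)
  p <- x^2
  nseg <- ncol(p) %/% spb
  vals <- matrix(0, nrow(p), nseg)
  for (i in seq_len(nrow(p))) {
    seg <- colMeans(matrix(p[i, seq_len(nseg * spb)], nrow = spb))
    vals[i, ] <- log10(moving_average_centered(seg, width))
  }
  structure(list(values = vals, feature_fs = 1 / segment_s, band = band,
                 segment_s = segment_s, labels = rec$labels,
                 events = rec$events, compensated = FALSE),
            class = "uhd_features")
}

#' @export
print.uhd_features <- function(x, ...) {
  cat(sprintf("band-power features: %d channels x %d samples @ %g Hz, band %g-%g Hz%s\n",
              nrow(x$values), ncol(x$values), x$feature_fs,
              x$band[1], x$band[2],
              if (x$compensated) ", drift-compensated" else ""))
  invisible(x)
}

#' Trailing power-shift compensation
#'
#' Subtracts from each log band-power sample the mean over the trailing
#' `window_s` seconds (inclusive of the current sample; shorter windows at
#' the stream start), per channel. Removes slow band-power drift that would
#' otherwise bias the classifier.
#'
#' @param features `uhd_features`.
#' @param window_s trailing window length in s (default 25).
#' @return compensated `uhd_features`.
#' @export
power_shift_compensation <- function(features, window_s = 25) {
  stopifnot(inherits(features, "uhd_features"))
  if (window_s < features$segment_s)
    stop("window_s must be at least one segment long")
  w <- as.integer(round(window_s * features$feature_fs))
  v <- features$values
  n <- ncol(v)
  lo <- pmax(seq_len(n) - w + 1L, 1L)
  len <- seq_len(n) - lo + 1L
  for (i in seq_len(nrow(v))) {
    cs <- cumsum(c(0, v[i, ]))
    v[i, ] <- v[i, ] - (cs[seq_len(n) + 1L] - cs[lo]) / len
  }
  features$values <- v
  features$compensated <- TRUE
  features$compensation_window_s <- window_s
  features
}

#' Epoch band-power features around task cues
#'
#' One epoch per task event; the cue is mapped to the feature-sample
#' boundary at or before cue onset, keeping the pre-cue reference strictly
#' pre-cue. Events too close to the stream boundary are dropped with a
#' warning.
#'
#' @param features `uhd_features`.
#' @param events event table (defaults to the one attached to `features`);
#'   task events are all trial types other than `"rest"`/`"baseline"`.
#' @param pre_s,post_s epoch window relative to cue (defaults 0.5 and 7).
#' @return object of class `uhd_epochs`: array trials x channels x
#'   epoch samples with attributes `labels` (finger per trial), `time_s`
#'   (per-sample time relative to cue), `feature_fs`, `channel_labels`,
#'   `band`.
#' @export
epoch_features <- function(features, events = NULL, pre_s = 0.5,
                           post_s = 7) {
  stopifnot(inherits(features, "uhd_features"))
  if (is.null(events)) events <- features$events
  task <- events[!events$trial_type %in% c("rest", "baseline"), ,
                 drop = FALSE]
  ffs <- features$feature_fs
  npre <- as.integer(round(pre_s * ffs))
  npost <- as.integer(round(post_s * ffs))
  len <- npre + npost
  n <- ncol(features$values)

  keep <- logical(nrow(task)); start <- integer(nrow(task))
  for (k in seq_len(nrow(task))) {
    cue_idx <- floor(task$onset[k] * ffs) + 1L  # first post-cue sample
    s0 <- cue_idx - npre
    keep[k] <- s0 >= 1L && (s0 + len - 1L) <= n
    start[k] <- s0
  }
  if (any(!keep))
    warning(sum(!keep), " trial(s) dropped: epoch outside feature stream")
  task <- task[keep, , drop = FALSE]; start <- start[keep]
  arr <- array(0, dim = c(nrow(task), nrow(features$values), len))
  for (k in seq_len(nrow(task)))
    arr[k, , ] <- features$values[, start[k]:(start[k] + len - 1L)]
  structure(arr,
            labels = task$trial_type,
            time_s = (seq_len(len) - npre - 1L) / ffs,
            feature_fs = ffs,
            channel_labels = features$labels,
            band = features$band,
            class = "uhd_epochs")
}

#' Concatenate epochs across runs
#'
#' @param epoch_list list of `uhd_epochs` with identical channel and time
#'   grids.
#' @return single `uhd_epochs`.
#' @export
bind_epochs <- function(epoch_list) {
  stopifnot(length(epoch_list) >= 1L)
  e1 <- epoch_list[[1]]
  nt <- sum(vapply(epoch_list, function(e) dim(e)[1], 0L))
  arr <- array(0, dim = c(nt, dim(e1)[2], dim(e1)[3]))
  labs <- character(0); at <- 0L
  for (e in epoch_list) {
    k <- dim(e)[1]
    if (k) arr[(at + 1L):(at + k), , ] <- e
    labs <- c(labs, attr(e, "labels"))
    at <- at + k
  }
  structure(arr, labels = labs, time_s = attr(e1, "time_s"),
            feature_fs = attr(e1, "feature_fs"),
            channel_labels = attr(e1, "channel_labels"),
            band = attr(e1, "band"), class = "uhd_epochs")
}

#' Concatenate epochs of several frequency bands along the channel axis
#'
#' @param band_list list of `uhd_epochs` (e.g. mu and beta) with identical
#'   trials and time grids.
#' @return `uhd_epochs` whose channel axis stacks all bands' channels.
#' @export
combine_bands <- function(band_list) {
  stopifnot(length(band_list) >= 1L)
  e1 <- band_list[[1]]
  arr <- array(0, dim = c(dim(e1)[1],
                          sum(vapply(band_list, function(e) dim(e)[2], 0L)),
                          dim(e1)[3]))
  labs <- character(0); at <- 0L
  for (e in band_list) {
    k <- dim(e)[2]
    arr[, (at + 1L):(at + k), ] <- e
    b <- attr(e, "band")
    labs <- c(labs, paste0(attr(e, "channel_labels"), "_",
                           b[1], "-", b[2]))
    at <- at + k
  }
  structure(arr, labels = attr(e1, "labels"), time_s = attr(e1, "time_s"),
            feature_fs = attr(e1, "feature_fs"),
            channel_labels = labs, band = NULL, class = "uhd_epochs")
}

#' @export
print.uhd_epochs <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("epoched features: %d trials x %d channels x %d samples (%g..%g s)\n",
              d[1], d[2], d[3], min(attr(x, "time_s")),
              max(attr(x, "time_s"))))
  invisible(x)
}

#' Export epochs as a tidy table
#'
#' @param epochs `uhd_epochs`.
#' @return data frame with columns `trial`, `channel`, `time_s`, `value`,
#'   `label`.
#' @export
epochs_to_table <- function(epochs) {
  d <- dim(epochs)
  data.frame(
    trial = rep(seq_len(d[1]), times = d[2] * d[3]),
    channel = rep(rep(attr(epochs, "channel_labels"), each = d[1]),
                  times = d[3]),
    time_s = rep(attr(epochs, "time_s"), each = d[1] * d[2]),
    value = as.vector(epochs),
    label = rep(attr(epochs, "labels"), times = d[2] * d[3]),
    stringsAsFactors = FALSE)
}
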