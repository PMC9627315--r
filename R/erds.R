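# Event-related desynchronization/synchronization (ERD/S): reference-window
# statistic in dB, scalp heatmap interpolation with a linear-decay kernel,
# focal electrode selection, and STFT time-frequency maps.

#' ERD/S map of the average trial
#'
#' Averages log band power over trials (per channel and time), subtracts
#' the per-channel mean over the reference window, and scales to dB
#' (x10, log10 features).
#'
#' @param epochs `uhd_epochs`.
#' @param reference_window_s reference window relative to cue (default
#'   `c(-0.5, 0)`, i.e. 0.5 to 0 s before the cue); samples with
#'   `start <= t < end` are used.
#' @param finger optional label: restrict to that finger's trials.
#' @return object of class `uhd_erds`: list with `values` (channels x
#'   epoch samples, dB), `time_s`, `reference_window_s`, `channel_labels`,
#'   `n_trials`.
#' @export
compute_erds <- function(epochs, reference_window_s = c(-0.5, 0),
                         finger = NULL) {
  stopifnot(inherits(epochs, "uhd_epochs"))
  tt <- attr(epochs, "time_s")
  labs <- attr(epochs, "labels")
  sel <- if (is.null(finger)) seq_along(labs) else which(labs == finger)
  if (length(sel) < 1L) stop("no trials selected")
  ref <- which(tt >= reference_window_s[1] & tt < reference_window_s[2])
  if (length(ref) == 0L) stop("empty reference window")
  avg <- apply(epochs[sel, , , drop = FALSE], c(2, 3), mean)  # ch x time
  vals <- 10 * (avg - rowMeans(avg[, ref, drop = FALSE]))
  structure(list(values = vals, time_s = tt,
                 reference_window_s = reference_window_s,
                 channel_labels = attr(epochs, "channel_labels"),
                 n_trials = length(sel)),
            class = "uhd_erds")
}

#' @export
print.uhd_erds <- function(x, ...) {
  cat(sprintf("ERD/S map: %d channels x %d samples (dB), %d trials, trough %.2f dB\n",
              nrow(x$values), ncol(x$values), x$n_trials, min(x$values)))
  invisible(x)
}

#' Focal electrode selection by ERD percentile
#'
#' Per finger: mean ERD/S over a post-cue window per electrode; electrodes
#' strictly below the `percentile`-th nearest-rank quantile of that
#' distribution (i.e. showing greater desynchronization than the rest) are
#' selected. On tie-free inputs this selects
#' `floor(percentile/100 * n_electrodes)` electrodes (6 of 256 at the
#' default 2.5).
#'
#' @param erds `uhd_erds` or a named list of them (one per finger).
#' @param window_s selection window relative to cue (default `c(1, 2)`).
#' @param percentile selection percentile in (0, 100) (default 2.5).
#' @return for a single map, an integer vector of selected electrode
#'   indices; for a list, a named list of such vectors.
#' @export
focal_selection <- function(erds, window_s = c(1, 2), percentile = 2.5) {
  if (!(is.numeric(percentile) && length(percentile) == 1L &&
        percentile > 0 && percentile < 100))
    stop("'percentile' must lie strictly between 0 and 100")
  if (inherits(erds, "uhd_erds")) {
    tt <- erds$time_s
    win <- which(tt >= window_s[1] & tt <= window_s[2])
    if (length(win) == 0L) stop("selection window outside epoch")
    m <- rowMeans(erds$values[, win, drop = FALSE])
    k <- floor(percentile / 100 * length(m))
    thr <- sort(m)[min(k + 1L, length(m))]
    which(m < thr)
  } else {
    lapply(erds, focal_selection, window_s = window_s,
           percentile = percentile)
  }
}

#' Quasi-uniform vertices on a hemispherical scalp surface
#'
#' Fibonacci lattice restricted to the upper hemisphere.
#'
#' @param n_vertices number of vertices.
#' @param radius_mm sphere radius (default 90).
#' @return matrix (n x 3) of vertex positions in mm.
#' @export
hemisphere_vertices <- function(n_vertices = 2000, radius_mm = 90) {
  i <- seq_len(2L * n_vertices) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - i / n_vertices          # upper hemisphere: z in (0, 1]
  keep <- z > 0
  r <- sqrt(1 - z[keep]^2)
  radius_mm * cbind(r * cos(phi[keep]), r * sin(phi[keep]), z[keep])
}

#' Scalp heatmap by linear-decay kernel interpolation
#'
#' Each electrode's activation is spread over surface vertices with a
#' linear kernel that is 1 at the electrode and reaches 0 at the Euclidean
#' distance to its closest (included) electrode; per-vertex contributions
#' are summed. Bad channels are excluded from the interpolation by default,
#' or set to activation 0 with `bad_mode = "zero"`.
#'
#' @param activation per-electrode scalar (e.g. ERD/S at one time point).
#' @param montage `uhd_montage`.
#' @param vertices matrix (n x 3) of surface vertices (default: hemisphere
#'   at the montage radius).
#' @param bad logical channel mask of bad channels (default none).
#' @param bad_mode `"exclude"` (default) or `"zero"`.
#' @return object of class `uhd_heatmap`: list with `vertices`,
#'   `activation` (per vertex), `kernel_radii` (per included electrode).
#' @export
surface_heatmap <- function(activation, montage, vertices = NULL,
                            bad = NULL, bad_mode = c("exclude", "zero")) {
  bad_mode <- match.arg(bad_mode)
  pos <- montage_positions(montage)
  stopifnot(length(activation) == nrow(pos))
  if (is.null(vertices)) {
    R <- attr(montage, "radius_mm")
    if (is.na(R)) stop("supply 'vertices' for montages without a radius")
    vertices <- hemisphere_vertices(radius_mm = R)
  }
  if (nrow(vertices) == 0L) stop("vertex set must be non-empty")
  if (is.null(bad)) bad <- rep(FALSE, nrow(pos))
  if (bad_mode == "zero") {
    activation[bad] <- 0
    bad <- rep(FALSE, nrow(pos))
  }
  keep <- which(!bad)
  out <- numeric(nrow(vertices))
  radii <- rep(NA_real_, nrow(pos))
  if (length(keep) >= 2L) {
    D <- as.matrix(stats::dist(pos[keep, , drop = FALSE]))
    diag(D) <- Inf
    for (ii in seq_along(keep)) {
      e <- keep[ii]
      d_e <- min(D[ii, ])
      radii[e] <- d_e
      dv <- sqrt(colSums((t(vertices) - pos[e, ])^2))
      w <- pmax(0, 1 - dv / d_e)
      out <- out + activation[e] * w
    }
  }
  structure(list(vertices = vertices, activation = out,
                 kernel_radii = radii),
            class = "uhd_heatmap")
}

#' Export a heatmap as a per-vertex table
#'
#' @param heatmap `uhd_heatmap`.
#' @return data frame with columns `x`, `y`, `z`, `value`.
#' @export
heatmap_to_table <- function(heatmap) {
  data.frame(x = heatmap$vertices[, 1], y = heatmap$vertices[, 2],
             z = heatmap$vertices[, 3], value = heatmap$activation)
}

# Bilinear image upsampling by an integer factor (display smoothing for
# time-frequency maps).
upsample_bilinear <- function(img, factor) {
  if (factor <= 1L) return(img)
  nr <- nrow(img); nc <- ncol(img)
  ri <- seq(1, nr, length.out = nr * factor)
  ci <- seq(1, nc, length.out = nc * factor)
  r0 <- pmin(floor(ri), nr - 1L); c0 <- pmin(floor(ci), nc - 1L)
  fr <- ri - r0; fc <- ci - c0
  img[r0, c0] * outer(1 - fr, 1 - fc) +
    img[r0 + 1L, c0] * outer(fr, 1 - fc) +
    img[r0, c0 + 1L] * outer(1 - fr, fc) +
    img[r0 + 1L, c0 + 1L] * outer(fr, fc)
}

#' Time-frequency ERD/S map for one channel
#'
#' Short-time Fourier transform power (1 Hz bins from a 1 s Hamming window
#' with 0.95 s overlap, i.e. a 20 Hz frame rate at the defaults), log10
#' transformed, epoched around task cues, averaged over trials, and
#' converted to ERD/S in dB against a pre-cue reference window.
#'
#' @param rec preprocessed `uhd_recording`.
#' @param channel channel index.
#' @param events event table (defaults to the recording's).
#' @param f_range frequency range in Hz (default `c(8, 30)`).
#' @param window_s STFT window length (default 1).
#' @param overlap_s STFT window overlap (default 0.95).
#' @param pre_s,post_s epoch window (defaults 1 and 7).
#' @param reference_window_s ERD/S reference (default `c(-1, 0)`).
#' @param interp integer display upsampling factor applied bilinearly in
#'   both axes (default 10; the raw map is always returned too).
#' @return object of class `uhd_tfmap`: list with `freq_hz`, `time_s`,
#'   `values` (freq x time, dB), `display` (upsampled image), `frame_fs`,
#'   `n_trials`.
#' @export
time_frequency_erds <- function(rec, channel, events = NULL,
                                f_range = c(8, 30), window_s = 1,
                                overlap_s = 0.95, pre_s = 1, post_s = 7,
                                reference_window_s = c(-1, 0),
                                interp = 10) {
  stopifnot(inherits(rec, "uhd_recording"))
  if (channel < 1 || channel > nrow(rec$data)) stop("invalid channel")
  nwin <- as.integer(round(window_s * rec$fs))
  if (nwin > ncol(rec$data)) stop("STFT window longer than recording")
  nov <- as.integer(round(overlap_s * rec$fs))
  step <- nwin - nov
  sp <- signal::specgram(rec$data[channel, ], n = nwin, Fs = rec$fs,
                         window = signal::hamming(nwin), overlap = nov)
  pow <- log10(Mod(sp$S)^2 + .Machine$double.xmin)
  fsel <- which(sp$f >= f_range[1] & sp$f <= f_range[2])
  pow <- pow[fsel, , drop = FALSE]
  frame_fs <- rec$fs / step
  ft <- sp$t                        # frame time stamps (s)

  if (is.null(events)) events <- rec$events
  task <- events[!events$trial_type %in% c("rest", "baseline"), ,
                 drop = FALSE]
  npre <- as.integer(round(pre_s * frame_fs))
  npost <- as.integer(round(post_s * frame_fs))
  len <- npre + npost
  acc <- matrix(0, length(fsel), len); ntr <- 0L
  for (k in seq_len(nrow(task))) {
    cue <- task$onset[k]
    i0 <- max(which(ft <= cue))     # frame at or before cue
    if (i0 - npre < 1L || i0 + npost - 1L > ncol(pow)) next
    acc <- acc + pow[, (i0 - npre + 1L):(i0 + npost), drop = FALSE]
    ntr <- ntr + 1L
  }
  if (ntr == 0L) stop("no epochable trials for the time-frequency map")
  avg <- acc / ntr
  rel_t <- (seq_len(len) - npre - 1L) / frame_fs
  ref <- which(rel_t >= reference_window_s[1] & rel_t < reference_window_s[2])
  vals <- 10 * (avg - rowMeans(avg[, ref, drop = FALSE]))
  structure(list(freq_hz = sp$f[fsel], time_s = rel_t, values = vals,
                 display = upsample_bilinear(vals, as.integer(interp)),
                 frame_fs = frame_fs, n_trials = ntr),
            class = "uhd_tfmap")
}

#' @export
print.uhd_tfmap <- function(x, ...) {
  cat(sprintf("time-frequency ERD/S: %d freqs x %d frames @ %g Hz, %d trials\n",
              length(x$freq_hz), length(x$time_s), x$frame_fs, x$n_trials))
  invisible(x)
}
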