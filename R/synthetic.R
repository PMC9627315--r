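# Synthetic uHD-EEG generator: cued single-finger extension paradigm and
# raw recordings with the statistical structure the analysis assumes
# (finger-specific mu/beta ERD with beta rebound, pink background noise,
# line noise, slow band-power drift, injected bad channels).

#' Define the experimental paradigm
#'
#' Cued single-finger extensions: each run starts with a baseline period,
#' then alternating rest (uniformly random duration) and task periods; every
#' finger is cued a fixed number of times per run in pseudo-random order.
#'
#' @param runs number of runs.
#' @param trials_per_finger cues per finger per run.
#' @param rest_range_s rest duration range (s), uniform.
#' @param task_s task (extension) duration (s).
#' @param baseline_s run-initial baseline duration (s).
#' @param fingers ordered finger labels.
#' @return object of class `uhd_paradigm` (a list of the above).
#' @export
paradigm_spec <- function(runs = 10, trials_per_finger = 5,
                          rest_range_s = c(3, 4), task_s = 5,
                          baseline_s = 30,
                          fingers = c("thumb", "index", "middle",
                                      "ring", "little")) {
  stopifnot(runs >= 1, trials_per_finger >= 0,
            length(rest_range_s) == 2L, rest_range_s[1] > 0,
            rest_range_s[1] <= rest_range_s[2], task_s > 0, baseline_s > 0,
            length(fingers) >= 1, !anyDuplicated(fingers))
  structure(list(runs = as.integer(runs),
                 trials_per_finger = as.integer(trials_per_finger),
                 rest_range_s = rest_range_s, task_s = task_s,
                 baseline_s = baseline_s, fingers = fingers),
            class = "uhd_paradigm")
}

#' Generate the paradigm event table
#'
#' @param paradigm `uhd_paradigm`.
#' @param seed integer seed; the cue order is a seeded permutation with each
#'   finger appearing exactly `trials_per_finger` times per run.
#' @return data frame with columns `run` (1-based), `onset` (s), `duration`
#'   (s), `trial_type` (`"baseline"`, `"rest"`, or a finger label).
#' @export
generate_paradigm <- function(paradigm, seed = 1) {
  stopifnot(inherits(paradigm, "uhd_paradigm"))
  p <- paradigm
  with_seed(seed, {
    out <- vector("list", p$runs)
    for (r in seq_len(p$runs)) {
      cues <- rep(p$fingers, times = p$trials_per_finger)
      if (length(cues) > 1L) cues <- sample(cues)
      onset <- 0
      ev <- list(data.frame(run = r, onset = 0, duration = p$baseline_s,
                            trial_type = "baseline"))
      onset <- p$baseline_s
      for (cue in cues) {
        rest <- stats::runif(1, p$rest_range_s[1], p$rest_range_s[2])
        ev[[length(ev) + 1L]] <- data.frame(
          run = r, onset = c(onset, onset + rest),
          duration = c(rest, p$task_s),
          trial_type = c("rest", cue))
        onset <- onset + rest + p$task_s
      }
      out[[r]] <- do.call(rbind, ev)
    }
    ev <- do.call(rbind, out)
    rownames(ev) <- NULL
    ev
  })
}

#' Default finger source centers for a montage
#'
#' Places the five finger-specific source centers on neighboring interior
#' electrodes along the central lattice row of the patch, two lattice steps
#' apart (a somatotopy-like strip over the hand-area analog).
#'
#' @param montage `uhd_montage` with lattice `row`/`col` columns.
#' @param n_fingers number of sources.
#' @return integer vector of electrode indices.
#' @export
default_finger_centers <- function(montage, n_fingers = 5) {
  rows <- montage$row; cols <- montage$col
  roi_rows <- range(rows[montage$roi]); roi_cols <- range(cols[montage$roi])
  r0 <- round(mean(roi_rows))
  c0 <- mean(roi_cols)
  # two lattice steps apart when the ROI is wide enough, else spread evenly
  want <- c0 + 2 * (seq_len(n_fingers) - (n_fingers + 1) / 2)
  if (want[1] < roi_cols[1] || want[n_fingers] > roi_cols[2])
    want <- seq(roi_cols[1], roi_cols[2], length.out = n_fingers)
  vapply(round(want), function(s) {
    which.min((rows - r0)^2 + (cols - s)^2)
  }, integer(1))
}

#' Specify synthetic effect structure and noise model
#'
#' @param montage `uhd_montage` (used for default source centers).
#' @param centers integer electrode indices of the five finger sources.
#' @param radius_mm linear spatial decay radius of each source (mm).
#' @param mu_erd_db,beta_erd_db ERD depth in band-power dB (<= 0).
#' @param mu_window_s,beta_window_s ERD window (s relative to cue).
#' @param rebound_db post-movement beta rebound magnitude (dB, >= 0).
#' @param rebound_window_s rebound window (s relative to cue).
#' @param mu_amp,beta_amp source oscillation amplitudes (microvolt SD).
#' @param pink_amp pink-noise amplitude per channel (microvolt SD).
#' @param line_amp shared 60 Hz line-noise amplitude (microvolt).
#' @param drift_db stationary SD of the slow log-band-power drift (dB).
#' @param drift_tau_s drift correlation time (s).
#' @param bad_channels integer channel indices replaced by artifact noise.
#' @param bad_gain artifact amplitude gain relative to `pink_amp`.
#' @return object of class `uhd_effects`.
#' @export
effect_spec <- function(montage, centers = NULL, radius_mm = 20,
                        mu_erd_db = -3, beta_erd_db = -2.5,
                        mu_window_s = c(0.5, 2.5),
                        beta_window_s = c(0.5, 5),
                        rebound_db = 2, rebound_window_s = c(6, 7),
                        mu_amp = 20, beta_amp = 15,
                        pink_amp = 10, line_amp = 5,
                        drift_db = 1, drift_tau_s = 60,
                        bad_channels = integer(0), bad_gain = 50) {
  if (is.null(centers)) centers <- default_finger_centers(montage)
  stopifnot(radius_mm > 0, mu_erd_db <= 0, beta_erd_db <= 0,
            rebound_db >= 0, mu_amp >= 0, beta_amp >= 0, pink_amp > 0)
  structure(list(centers = centers, radius_mm = radius_mm,
                 mu_erd_db = mu_erd_db, beta_erd_db = beta_erd_db,
                 mu_window_s = mu_window_s, beta_window_s = beta_window_s,
                 rebound_db = rebound_db,
                 rebound_window_s = rebound_window_s,
                 mu_amp = mu_amp, beta_amp = beta_amp,
                 pink_amp = pink_amp, line_amp = line_amp,
                 drift_db = drift_db, drift_tau_s = drift_tau_s,
                 bad_channels = bad_channels, bad_gain = bad_gain),
            class = "uhd_effects")
}

# Pink (1/f amplitude spectrum) noise of length n, unit SD. Synthesized at
# a highly composite FFT length and truncated, for speed.
pink_noise <- function(n) {
  nn <- stats::nextn(n)
  nf <- nn %/% 2L
  f <- seq_len(nf)
  amp <- 1 / sqrt(f)
  ph <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = ph)
  full <- complex(real = numeric(nn))
  full[2:(nf + 1L)] <- spec
  full[nn:(nn - nf + 2L)] <- Conj(spec[seq_len(nf - 1L)])
  x <- Re(stats::fft(full, inverse = TRUE))[seq_len(n)]
  x / stats::sd(x)
}

# Band-limited oscillation of length n, unit SD (zero-phase filtered white
# noise).
band_oscillation <- function(n, band, fs) {
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  x <- as.numeric(signal::filtfilt(bf, stats::rnorm(n)))
  x / stats::sd(x)
}

# Amplitude envelope realizing a dB band-power change inside
# [t0, t1] (absolute seconds) with raised-cosine ramps.
apply_gain_window <- function(env, t, t0, t1, gain_db, ramp_s = 0.25) {
  a <- 10^(gain_db / 20)
  g <- rep(1, length(t))
  core <- t >= t0 + ramp_s & t <= t1 - ramp_s
  g[core] <- a
  up <- t >= t0 & t < t0 + ramp_s
  g[up] <- 1 + (a - 1) * (1 - cos(pi * (t[up] - t0) / ramp_s)) / 2
  dn <- t > t1 - ramp_s & t <= t1
  g[dn] <- 1 + (a - 1) * (1 - cos(pi * (t1 - t[dn]) / ramp_s)) / 2
  env * g
}

#' Synthesize a raw uHD-EEG recording for one run
#'
#' Background is per-channel pink noise plus a shared 60 Hz sinusoid and a
#' slow multiplicative band-power drift. Ongoing mu and beta oscillations
#' are mixed into the channels from finger-specific sources with linear
#' amplitude decay over `radius_mm`; during each task event the cued
#' finger's source amplitude is scaled to realize the specified ERD depth
#' (band power scales with amplitude squared), followed by the beta
#' rebound. Bad channels are replaced by high-variance noise.
#'
#' @param montage `uhd_montage`.
#' @param events event table for one run (columns `onset`, `duration`,
#'   `trial_type`).
#' @param effects `uhd_effects`.
#' @param fs sampling frequency (Hz, >= 200).
#' @param seed integer seed; the recording is deterministic given all
#'   arguments.
#' @return `uhd_recording`.
#' @export
synthesize_recording <- function(montage, events, effects, fs = 600,
                                 seed = 1) {
  stopifnot(inherits(montage, "uhd_montage"), inherits(effects, "uhd_effects"))
  if (fs < 200) stop("'fs' must be at least 200 Hz")
  if (nrow(events) == 0L) stop("event table must be non-empty")
  fingers <- c("thumb", "index", "middle", "ring", "little")
  known <- c("baseline", "rest", fingers)
  if (!all(events$trial_type %in% known))
    stop("invalid event trial_type: ",
         paste(setdiff(events$trial_type, known), collapse = ", "))

  nch <- nrow(montage)
  # tail long enough that the last trial's 7 s post-cue epoch fits
  dur <- max(events$onset + events$duration) + 3
  n <- ceiling(dur * fs)
  t <- (seq_len(n) - 1L) / fs

  with_seed(seed, {
    x <- matrix(0, nch, n)
    for (c_ in seq_len(nch)) x[c_, ] <- effects$pink_amp * pink_noise(n)
    if (effects$line_amp > 0)
      x <- x + rep(effects$line_amp * sin(2 * pi * 60 * t),
                   each = nch)

    # finger-specific sources, spatially mixed with linear decay
    pos <- montage_positions(montage)
    nf <- length(effects$centers)
    centers <- effects$centers
    task <- events[events$trial_type %in% fingers, , drop = FALSE]
    for (f in seq_len(nf)) {
      d <- sqrt(colSums((t(pos) - pos[centers[f], ])^2))
      w <- pmax(0, 1 - d / effects$radius_mm)
      if (all(w == 0)) next
      ev_f <- task[task$trial_type == fingers[f], , drop = FALSE]
      env_mu <- rep(1, n); env_beta <- rep(1, n)
      for (k in seq_len(nrow(ev_f))) {
        on <- ev_f$onset[k]
        env_mu <- apply_gain_window(env_mu, t, on + effects$mu_window_s[1],
                                    on + effects$mu_window_s[2],
                                    effects$mu_erd_db)
        env_beta <- apply_gain_window(env_beta, t,
                                      on + effects$beta_window_s[1],
                                      on + effects$beta_window_s[2],
                                      effects$beta_erd_db)
        if (effects$rebound_db > 0)
          env_beta <- apply_gain_window(env_beta, t,
                                        on + effects$rebound_window_s[1],
                                        on + effects$rebound_window_s[2],
                                        effects$rebound_db)
      }
      src <- effects$mu_amp * band_oscillation(n, c(8, 12), fs) * env_mu +
        effects$beta_amp * band_oscillation(n, c(13, 25), fs) * env_beta
      x <- x + outer(w, src)
    }

    # slow multiplicative band-power drift: OU process on the dB scale,
    # simulated at 1 Hz and linearly interpolated to the sample rate
    if (effects$drift_db > 0) {
      nk <- max(2L, ceiling(dur) + 1L)
      rho <- exp(-1 / effects$drift_tau_s)
      innov_sd <- effects$drift_db * sqrt(1 - rho^2)
      for (c_ in seq_len(nch)) {
        dvals <- numeric(nk)
        dvals[1] <- stats::rnorm(1, 0, effects$drift_db)
        for (k in 2:nk)
          dvals[k] <- rho * dvals[k - 1L] + stats::rnorm(1, 0, innov_sd)
        dchan <- stats::approx(seq_len(nk) - 1L, dvals, xout = t,
                               rule = 2)$y
        x[c_, ] <- x[c_, ] * 10^(dchan / 20)
      }
    }

    if (length(effects$bad_channels)) {
      for (c_ in effects$bad_channels)
        x[c_, ] <- effects$bad_gain * effects$pink_amp * stats::rnorm(n)
    }

    recording(x, fs, montage$label, events)
  })
}

#' Built-in synthetic study presets
#'
#' Bundles a montage, paradigm, and effect specification at desk scale:
#' * `"demo"`: 4 grids (64 channels), 3 runs of 25 trials, 600 Hz, default
#'   ERD depths (-3 dB mu, -2.5 dB beta).
#' * `"strong"`: 9 grids (144 channels), 5 runs, 200 Hz, -4 dB ERD in both
#'   bands with finger sources two lattice steps apart -- a strong, focal
#'   effect for decoding checks.
#' * `"null"`: 1 grid (16 channels), a single run of 40 trials, 200 Hz,
#'   ERD depth 0 (no task-related modulation) for statistical calibration;
#'   single-run so that the cue order is exchangeable with label
#'   permutations (no run-block structure a permuted-label model could
#'   exploit).
#' * `"full"`: the full study geometry (16 grids, 256 channels, 10 runs of
#'   25 trials at 600 Hz).
#'
#' @param name preset name.
#' @return list with elements `montage`, `paradigm`, `effects`, `fs`.
#' @export
synthetic_preset <- function(name = c("demo", "strong", "null", "full")) {
  name <- switch(match.arg(name),
    demo = {
      m <- build_uhd_montage(n_grids = 4)
      list(montage = m,
           paradigm = paradigm_spec(runs = 3),
           effects = effect_spec(m),
           fs = 600)
    },
    strong = {
      m <- build_uhd_montage(n_grids = 9)
      list(montage = m,
           paradigm = paradigm_spec(runs = 5),
           effects = effect_spec(m, mu_erd_db = -4, beta_erd_db = -4),
           fs = 200)
    },
    null = {
      m <- build_uhd_montage(n_grids = 1)
      list(montage = m,
           paradigm = paradigm_spec(runs = 1, trials_per_finger = 8),
           effects = effect_spec(m, centers = default_finger_centers(m),
                                 mu_erd_db = 0, beta_erd_db = 0,
                                 rebound_db = 0),
           fs = 200)
    },
    full = {
      m <- build_uhd_montage(n_grids = 16)
      list(montage = m,
           paradigm = paradigm_spec(runs = 10),
           effects = effect_spec(m),
           fs = 600)
    })
  name
}

#' Synthesize all runs of a study
#'
#' @param preset list as returned by [synthetic_preset()] (or assembled
#'   manually from a montage, paradigm, effects, and `fs`).
#' @param seed integer base seed; run `r` uses `seed + r`.
#' @return list with `runs` (list of `uhd_recording`, one per run),
#'   `events` (full event table with `run` column), and the preset pieces.
#' @export
synthesize_study <- function(preset, seed = 1) {
  ev <- generate_paradigm(preset$paradigm, seed)
  runs <- lapply(seq_len(preset$paradigm$runs), function(r) {
    ev_r <- ev[ev$run == r, c("onset", "duration", "trial_type")]
    rownames(ev_r) <- NULL
    synthesize_recording(preset$montage, ev_r, preset$effects,
                         fs = preset$fs, seed = seed + r)
  })
  list(runs = runs, events = ev, montage = preset$montage,
       paradigm = preset$paradigm, effects = preset$effects,
       fs = preset$fs)
}
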