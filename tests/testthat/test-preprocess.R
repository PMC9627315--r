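test_that("resampling preserves length, DC, and sinusoid amplitude", {
  # 600 samples at 600 Hz -> 200 samples at 200 Hz
  rec <- recording(matrix(rnorm(2 * 600), 2), 600)
  out <- resample_recording(rec, 200)
  expect_equal(ncol(out$data), 200)
  expect_equal(out$fs, 200)

  # constant signal preserved away from edge transients
  recc <- recording(matrix(2.5, 1, 6000), 600)
  outc <- resample_recording(recc, 200)
  n <- ncol(outc$data)
  edge <- ceiling(0.01 * n)
  inner <- outc$data[1, (edge + 1):(n - edge)]
  expect_lt(max(abs(inner - 2.5)), 0.025)

  # analytic sinusoid oracle: 10 Hz amplitude preserved within 1%
  t6 <- (0:5999) / 600
  recs <- recording(matrix(sin(2 * pi * 10 * t6), 1), 600)
  outs <- resample_recording(recs, 200)
  t2 <- (seq_len(ncol(outs$data)) - 1) / 200
  mid <- t2 > 1 & t2 < 9
  expect_lt(max(abs(outs$data[1, mid] - sin(2 * pi * 10 * t2[mid]))),
            0.01)

  expect_error(resample_recording(rec, 600), "smaller")
  expect_error(resample_recording(rec, 900), "smaller")
})

test_that("notch cascade removes line harmonics and passes the passband", {
  # fs 200: single notch at 60 Hz; 60 Hz power reduced >= 100x
  t2 <- (0:3999) / 200
  rec <- recording(matrix(sin(2 * pi * 60 * t2), 1), 200)
  out <- notch_cascade(rec, 60)
  late <- t2 > 5
  expect_lt(mean(out$data[1, late]^2) / mean(rec$data[1, late]^2), 0.01)

  # 10 Hz sinusoid passes within 5%
  rec10 <- recording(matrix(sin(2 * pi * 10 * t2), 1), 200)
  out10 <- notch_cascade(rec10, 60)
  expect_lt(max(abs(out10$data[1, late] - rec10$data[1, late])), 0.05)

  # fs 600: harmonics 60, 120, 180, 240 all strictly below Nyquist removed
  t6 <- (0:5999) / 600
  x <- rowSums(sapply(c(60, 120, 180, 240), function(f)
    sin(2 * pi * f * t6)))
  rec6 <- recording(matrix(x, 1), 600)
  out6 <- notch_cascade(rec6, 60)
  expect_lt(mean(out6$data[1, t6 > 5]^2) / mean(x[t6 > 5]^2), 0.01)

  expect_error(notch_cascade(rec, 100), "Nyquist")
})

# direct re-implementation of the bad-channel statistic (plain loops)
brute_z <- function(x, fs, task, band = c(8, 25)) {
  x <- sweep(x, 2, colMeans(x))
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  for (i in seq_len(nrow(x)))
    x[i, ] <- as.numeric(signal::filter(bf$b, bf$a, x[i, ]))
  keep <- rep(FALSE, ncol(x))
  for (k in seq_len(nrow(task))) {
    i0 <- floor(task$onset[k] * fs) + 1
    i1 <- min(ncol(x), ceiling((task$onset[k] + task$duration[k]) * fs))
    keep[i0:i1] <- TRUE
  }
  lp <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    v <- x[i, keep]
    lp[i] <- log10(mean((v - mean(v))^2))
  }
  (lp - mean(lp)) / sd(lp)
}

test_that("bad-channel z-scores match a brute-force oracle", {
  set.seed(1)
  fs <- 200
  x <- matrix(rnorm(32 * 30 * fs), 32)
  x[17, ] <- 100 * x[17, ]
  ev <- data.frame(onset = c(5, 15), duration = c(5, 5),
                   trial_type = c("index", "ring"))
  rec <- recording(x, fs, events = ev)
  rep_ <- identify_bad_channels(list(rec), threshold_z = 5)
  expect_equal(rep_$z_scores[, 1], brute_z(x, fs, ev), tolerance = 1e-10)
  expect_equal(which(rep_$bad_channels), 17L)
  expect_equal(which.max(rep_$z_scores[, 1]), 17L)
})

test_that("bad-channel detection is scale-equivariant", {
  set.seed(2)
  fs <- 200
  x <- matrix(rnorm(16 * 20 * fs), 16)
  ev <- data.frame(onset = 5, duration = 10, trial_type = "thumb")
  z1 <- identify_bad_channels(list(recording(x, fs, events = ev)),
                              threshold_z = 10)$z_scores
  z2 <- identify_bad_channels(list(recording(7.3 * x, fs, events = ev)),
                              threshold_z = 10)$z_scores
  expect_equal(z1, z2, tolerance = 1e-9)
})

test_that("runs with more than the bad fraction of channels are removed", {
  set.seed(3)
  fs <- 200
  mk_run <- function(bad = integer(0)) {
    x <- matrix(rnorm(20 * 20 * fs), 20)
    x[bad, ] <- 50 * x[bad, , drop = FALSE]
    recording(x, fs, events = data.frame(onset = 5, duration = 10,
                                         trial_type = "index"))
  }
  # 3 of 20 bad channels = 15% > 10% -> run flagged; thresholds chosen so
  # the 3 outliers are detectable among 20 channels
  runs <- list(mk_run(), mk_run(bad = c(2, 9, 15)))
  rep_ <- identify_bad_channels(runs, threshold_z = 2, run_fraction = 0.1)
  expect_true(rep_$bad_runs[2])
  expect_false(rep_$bad_runs[1])
  # flagged run is excluded from the cross-run disjunction
  expect_false(any(rep_$bad_channels[c(2, 9, 15)]))
})

test_that("a channel bad in one retained run is bad in all runs", {
  set.seed(4)
  fs <- 200
  mk_run <- function(bad = integer(0)) {
    x <- matrix(rnorm(64 * 20 * fs), 64)
    x[bad, ] <- 40 * x[bad, , drop = FALSE]
    recording(x, fs, events = data.frame(onset = 5, duration = 10,
                                         trial_type = "index"))
  }
  runs <- list(mk_run(), mk_run(bad = 33), mk_run())
  rep_ <- identify_bad_channels(runs)
  expect_false(any(rep_$bad_runs))
  expect_equal(which(rep_$bad_channels), 33L)
  expect_gt(rep_$z_scores[33, 2], 6)
})

test_that("detector finds every injected bad channel with no false alarms", {
  m <- build_uhd_montage(16)
  par <- paradigm_spec(runs = 1, trials_per_finger = 1)
  hits <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    bad <- sort(sample(seq_len(nrow(m)), 2))
    eff <- effect_spec(m, bad_channels = bad)  # default artifact gain
    st <- synthesize_study(list(montage = m, paradigm = par,
                                effects = eff, fs = 200), seed = s)
    rep_ <- identify_bad_channels(st$runs)
    identical(which(rep_$bad_channels), bad)
  }, TRUE)
  expect_equal(sum(hits), 20)
})

test_that("common average referencing behaves per definition", {
  x <- rbind(rep(1, 100), rep(-1, 100))
  rec <- recording(x, 100)
  out <- apply_car(rec)
  expect_equal(out$data, x)  # zero-mean fixed point

  set.seed(5)
  rec2 <- recording(matrix(rnorm(5 * 200), 5), 100)
  out2 <- apply_car(rec2)
  expect_lt(max(abs(colMeans(out2$data))), 1e-12)

  # exclusion: dropped channel absent, remaining re-referenced exactly
  x3 <- matrix(rnorm(3 * 50), 3)
  rec3 <- recording(x3, 100)
  out3 <- apply_car(rec3, exclude = c(FALSE, FALSE, TRUE))
  expect_equal(nrow(out3$data), 2)
  expect_equal(out3$data,
               sweep(x3[1:2, ], 2, colMeans(x3[1:2, ])),
               tolerance = 1e-12)
  expect_equal(out3$labels, rec3$labels[1:2])
  expect_error(apply_car(rec3, exclude = c(TRUE, TRUE, FALSE)),
               "at least 2")
})

test_that("full preprocessing is deterministic", {
  set.seed(6)
  x <- matrix(rnorm(8 * 20 * 600), 8)
  ev <- data.frame(onset = c(5, 12), duration = c(5, 5),
                   trial_type = c("index", "thumb"))
  runs <- list(recording(x, 600, events = ev))
  a <- preprocess_study(runs, fs_out = 200, threshold_z = 10)
  b <- preprocess_study(runs, fs_out = 200, threshold_z = 10)
  expect_identical(a$runs[[1]]$data, b$runs[[1]]$data)
  expect_identical(a$report$z_scores, b$report$z_scores)
})
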