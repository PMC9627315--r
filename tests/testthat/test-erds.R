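test_that("ERD/S is zero for unmodulated features and zero-mean in reference", {
  ep <- toy_epochs(n_per_class = 5, n_channels = 4, n_time = 30)
  ep[] <- 1.25   # constant over time and trials
  er <- compute_erds(ep)
  expect_equal(er$values, matrix(0, 4, 30), tolerance = 1e-12)

  # reference zero-mean invariant holds exactly for any input
  ep2 <- toy_epochs(n_per_class = 6, n_channels = 5, n_time = 30, shift = 1)
  er2 <- compute_erds(ep2)
  ref <- attr(ep2, "time_s") >= -0.5 & attr(ep2, "time_s") < 0
  expect_lt(max(abs(rowMeans(er2$values[, ref]))), 1e-9)

  expect_error(compute_erds(ep, reference_window_s = c(-5, -4)), "empty")
})

test_that("injected mu ERD depth is recovered from the average trial", {
  fx <- fixture("erd_recovery", function() {
    m <- build_uhd_montage(4)
    eff <- effect_spec(m)
    par <- paradigm_spec(runs = 2, trials_per_finger = 25,
                         fingers = "middle")
    st <- synthesize_study(list(montage = m, paradigm = par,
                                effects = eff, fs = 200), seed = 1)
    pre <- preprocess_study(st$runs, fs_out = NULL)
    eps <- bind_epochs(lapply(pre$runs, function(r)
      epoch_features(power_shift_compensation(band_power(r, c(8, 12))))))
    list(eps = eps, center = eff$centers[3])
  })
  er <- compute_erds(fx$eps, finger = "middle")
  expect_gte(er$n_trials, 25)
  tt <- er$time_s
  depth <- mean(er$values[fx$center, tt >= 1 & tt <= 2])
  expect_lt(abs(depth - (-3)), 1)
})

test_that("ERD and rebound windows show the expected sign pattern", {
  fx <- strong_epochs_fixture()
  beta <- compute_erds(fx$bands$beta, finger = "middle")
  mu <- compute_erds(fx$bands$mu, finger = "middle")
  ctr <- fx$study$effects$centers[3]
  tt <- beta$time_s
  # beta ERD during the task, rebound after movement end
  expect_lt(mean(beta$values[ctr, tt >= 1 & tt <= 4]), -1)
  expect_gt(mean(beta$values[ctr, tt >= 6.25 & tt <= 6.75]), 0.5)
  # mu ERD inside its window, none before the cue
  expect_lt(mean(mu$values[ctr, tt >= 1 & tt <= 2]), -1)
  expect_gt(mean(mu$values[ctr, tt >= 3.5 & tt <= 5]),
            mean(mu$values[ctr, tt >= 1 & tt <= 2]))
})

test_that("focal selection implements the strict percentile rule", {
  mk_erds <- function(v) structure(
    list(values = matrix(v, length(v), 5), time_s = seq(0.75, 1.75, 0.25),
         reference_window_s = c(-0.5, 0),
         channel_labels = as.character(seq_along(v)), n_trials = 1),
    class = "uhd_erds")

  # sorting oracle: values 1..100 at percentile 5 -> electrodes {1..5}
  sel <- focal_selection(mk_erds(1:100), window_s = c(0.75, 1.75),
                         percentile = 5)
  expect_equal(sel, 1:5)

  # 256 tie-free values at 2.5% -> 6 electrodes
  set.seed(11)
  v <- rnorm(256)
  sel256 <- focal_selection(mk_erds(v), window_s = c(0.75, 1.75),
                            percentile = 2.5)
  expect_equal(length(sel256), 6)
  expect_equal(sort(v[sel256]), sort(v)[1:6])

  # degenerate ties: all equal -> empty selection
  expect_equal(length(focal_selection(mk_erds(rep(1, 50)),
                                      window_s = c(0.75, 1.75))), 0)

  # count property floor(p/100 * n) on tie-free inputs
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(20:300, 1); p <- runif(1, 1, 20)
    sel <- focal_selection(mk_erds(rnorm(n)), window_s = c(0.75, 1.75),
                           percentile = p)
    expect_equal(length(sel), floor(p / 100 * n))
  }

  expect_error(focal_selection(mk_erds(1:10), percentile = 0), "between")
  expect_error(focal_selection(mk_erds(1:10), percentile = 100), "between")
})

test_that("heatmap kernel follows the linear-decay definition", {
  # single electrode: 1 at the electrode, 0.5 at half the kernel radius,
  # 0 beyond; kernel radius = distance to the closest electrode
  m <- planar_grid_montage(1, 5, spacing_mm = 10)[1:2, ]
  m$edge <- FALSE
  # electrodes sit at y = 0 and y = 10; probe vertices along that axis
  verts <- cbind(c(0, 0, 0, 0), c(0, 5, 11, 10), 0)
  hm <- surface_heatmap(c(1, 0), m, verts)
  expect_equal(hm$kernel_radii, c(10, 10))
  expect_equal(hm$activation, c(1, 0.5, 0, 0))

  # overlapping kernels: equal activation a, vertex midway -> a
  hm2 <- surface_heatmap(c(0.8, 0.8), m, verts)
  expect_equal(hm2$activation[2], 0.8)

  # all-bad montage -> all-zero heatmap
  hm3 <- surface_heatmap(c(1, 1), m, verts, bad = c(TRUE, TRUE))
  expect_equal(hm3$activation, rep(0, 4))

  # bad_mode zero keeps the channel in place with activation 0
  hm4 <- surface_heatmap(c(1, 1), m, verts, bad = c(FALSE, TRUE),
                         bad_mode = "zero")
  expect_equal(hm4$activation[1], 1)
  expect_equal(hm4$activation[3], 0)
})

test_that("heatmap is linear and matches a per-vertex brute force", {
  set.seed(12)
  n_e <- 15; n_v <- 400
  m <- planar_grid_montage(3, 5, spacing_mm = 12)
  m$x <- m$x + runif(n_e, -2, 2); m$y <- m$y + runif(n_e, -2, 2)
  verts <- cbind(runif(n_v, -10, 60), runif(n_v, -10, 40), 0)
  act <- rnorm(n_e)
  hm <- surface_heatmap(act, m, verts)

  pos <- as.matrix(m[, c("x", "y", "z")])
  brute <- numeric(n_v)
  for (v in seq_len(n_v)) {
    for (e in seq_len(n_e)) {
      d_e <- min(sqrt(rowSums(sweep(pos[-e, , drop = FALSE], 2,
                                    pos[e, ])^2)))
      dv <- sqrt(sum((verts[v, ] - pos[e, ])^2))
      if (dv < d_e) brute[v] <- brute[v] + act[e] * (1 - dv / d_e)
    }
  }
  expect_equal(hm$activation, brute, tolerance = 1e-12)

  # homogeneity
  hm2 <- surface_heatmap(3 * act, m, verts)
  expect_equal(hm2$activation, 3 * hm$activation, tolerance = 1e-12)
})

test_that("time-frequency map has the documented frame rate and null level", {
  # 1 s window with 0.95 s overlap -> 20 frames per second
  set.seed(13)
  fs <- 200
  dur <- 460
  ev <- data.frame(onset = seq(15, dur - 15, by = 8), duration = 5,
                   trial_type = "index")
  rec <- recording(matrix(rnorm(fs * dur), 1), fs, events = ev)
  tf <- time_frequency_erds(rec, channel = 1, interp = 1)
  expect_equal(tf$frame_fs, 20)
  expect_equal(tf$freq_hz, 8:30)
  expect_gte(tf$n_trials, 50)
  # stationary noise: mean ERD/S near 0 dB overall; the 0.95 s window
  # overlap leaves only ~2 independent reference frames per trial, so the
  # per-frequency mean keeps a sampling SD of ~0.5 dB at 50 trials
  expect_lt(abs(mean(tf$values)), 0.2)
  expect_lt(max(abs(rowMeans(tf$values))), 2)

  expect_error(time_frequency_erds(rec, channel = 99), "invalid channel")
  short <- recording(matrix(rnorm(50), 1), 200)
  expect_error(time_frequency_erds(short, 1), "longer than")
})

test_that("time-frequency map shows beta ERD then rebound", {
  fx <- strong_epochs_fixture()
  rec <- fx$pre$runs[[1]]
  ctr <- fx$study$effects$centers[3]
  ev <- rec$events
  ev <- ev[ev$trial_type == "middle", ]
  tf <- time_frequency_erds(rec, channel = ctr, events = ev, interp = 2)
  beta_rows <- tf$freq_hz >= 13 & tf$freq_hz <= 25
  task <- tf$time_s >= 1 & tf$time_s <= 4
  reb <- tf$time_s >= 6 & tf$time_s <= 7
  expect_lt(mean(tf$values[beta_rows, task]), -1)
  expect_gt(mean(tf$values[beta_rows, reb]),
            mean(tf$values[beta_rows, task]))
  # display upsampling doubles both axes
  expect_equal(dim(tf$display), 2 * dim(tf$values))
})
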