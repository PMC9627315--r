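# Shared fixtures, built lazily once per test session.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Strong-effect study processed to combined-band epochs (heaviest shared
# fixture: used by classification and ERD tests).
strong_epochs_fixture <- function() {
  fixture("strong_epochs", function() {
    st <- synthesize_study(synthetic_preset("strong"), seed = 1)
    pre <- preprocess_study(st$runs, fs_out = NULL)
    mont <- subset_montage(st$montage, pre$kept_channels,
                           recompute_edge = FALSE)
    bands <- lapply(list(mu = c(8, 12), beta = c(13, 25)), function(bd)
      bind_epochs(lapply(pre$runs, function(r)
        epoch_features(power_shift_compensation(band_power(r, bd))))))
    list(study = st, pre = pre, montage = mont, bands = bands,
         epochs = combine_bands(bands),
         roi = rep(mont$roi, 2))
  })
}

# Median neighbor correlation for the uHD patch and its density subsets,
# one row per seed (columns uhd, dense, sparse).
density_ordering_seeds <- function(seeds) {
  m <- build_uhd_montage(4)
  par <- paradigm_spec(runs = 1, trials_per_finger = 1)
  sp <- select_density_subset(m, "sparse")
  de <- select_density_subset(m, "dense")
  t(vapply(seeds, function(s) {
    eff <- effect_spec(m)
    st <- synthesize_study(list(montage = m, paradigm = par,
                                effects = eff, fs = 200), seed = 900 + s)
    pre <- preprocess_study(st$runs, fs_out = NULL)
    rec <- pre$runs[[1]]
    kept <- pre$kept_channels
    med_r <- function(mask, include_edge) {
      idx <- intersect(which(mask), kept)
      mm <- subset_montage(m, idx)
      g <- four_nearest_neighbors(mm, include_edge = include_edge)
      rs <- recording(rec$data[match(idx, kept), , drop = FALSE], rec$fs)
      ns <- neighbor_correlations(rs, g)
      ns$summary$median[ns$summary$metric == "r"]
    }
    c(uhd = med_r(rep(TRUE, nrow(m)), FALSE),
      dense = med_r(de, TRUE), sparse = med_r(sp, TRUE))
  }, c(uhd = 0, dense = 0, sparse = 0)))
}

# Mean peak decoding accuracy (over three representative finger pairs) for
# the full uHD ROI and the sparse density subset, one row per seed.
decode_ordering_seeds <- function(seeds) {
  m <- build_uhd_montage(4)
  pairs <- list(c("thumb", "little"), c("thumb", "middle"),
                c("index", "ring"))
  t(vapply(seeds, function(s) {
    eff <- effect_spec(m, mu_erd_db = -4, beta_erd_db = -4)
    st <- synthesize_study(list(montage = m,
                                paradigm = paradigm_spec(runs = 3),
                                effects = eff, fs = 200), seed = 500 + s)
    pre <- preprocess_study(st$runs, fs_out = NULL)
    mk <- subset_montage(m, pre$kept_channels, recompute_edge = FALSE)
    sparse <- select_density_subset(mk, "sparse")
    use <- mk$roi | sparse
    runs_use <- lapply(pre$runs, function(r)
      recording(r$data[use, , drop = FALSE], r$fs, r$labels[use],
                r$events))
    eps <- combine_bands(lapply(list(c(8, 12), c(13, 25)), function(bd)
      bind_epochs(lapply(runs_use, function(r)
        epoch_features(power_shift_compensation(band_power(r, bd)))))))
    roi_use <- rep(mk$roi[use], 2)
    sparse_use <- rep(sparse[use], 2)
    accs <- vapply(pairs, function(pp) c(
      pairwise_cv(eps, pair = pp, roi = roi_use, n_iterations = 3,
                  k_folds = 5)$peak_accuracy_mean,
      pairwise_cv(eps, pair = pp, roi = sparse_use, n_iterations = 3,
                  k_folds = 5)$peak_accuracy_mean), c(0, 0))
    c(full = mean(accs[1, ]), subset = mean(accs[2, ]))
  }, c(full = 0, subset = 0)))
}

# A white-noise recording with evenly spaced task events (no generator
# involvement; for filter/feature unit tests).
noise_recording <- function(n_channels = 4, dur_s = 60, fs = 200,
                            n_events = 5, seed = 42) {
  set.seed(seed)
  x <- matrix(rnorm(n_channels * dur_s * fs), n_channels)
  onsets <- seq(10, dur_s - 10, length.out = n_events)
  ev <- data.frame(onset = onsets, duration = 5,
                   trial_type = rep("index", n_events))
  recording(x, fs, events = ev)
}

# Hand-built epochs array with controllable class signal: trials x
# channels x samples, labels alternating between two classes, with a mean
# shift on `informative` channels during post-cue samples.
toy_epochs <- function(n_per_class = 12, n_channels = 6, n_time = 12,
                       shift = 0, informative = 1:2, seed = 7,
                       classes = c("a", "b"), feature_fs = 4,
                       pre_samples = 2) {
  set.seed(seed)
  nt <- 2 * n_per_class
  arr <- array(rnorm(nt * n_channels * n_time), c(nt, n_channels, n_time))
  labs <- rep(classes, n_per_class)
  post <- (pre_samples + 1):n_time
  arr[labs == classes[2], informative, post] <-
    arr[labs == classes[2], informative, post] + shift
  structure(arr, labels = labs,
            time_s = (seq_len(n_time) - pre_samples - 1) / feature_fs,
            feature_fs = feature_fs,
            channel_labels = sprintf("CH%02d", seq_len(n_channels)),
            band = c(8, 12), class = "uhd_epochs")
}
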