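test_that("pairwise CV separates classes with a known feature shift", {
  ep <- toy_epochs(n_per_class = 15, shift = 3, seed = 20)
  cv <- pairwise_cv(ep, n_iterations = 3, k_folds = 5,
                    time_window_s = c(0, 2.5))
  expect_s3_class(cv, "uhd_cv")
  expect_gt(cv$peak_accuracy_mean, 90)
  expect_true(all(cv$accuracy >= 0 & cv$accuracy <= 100))
  expect_equal(cv$peak_accuracy_mean, max(colMeans(cv$accuracy)))
  expect_equal(dim(cv$accuracy), c(3, 10))
})

test_that("CV is deterministic given seeds and symmetric in labels", {
  ep <- toy_epochs(n_per_class = 10, shift = 1, seed = 21)
  a <- pairwise_cv(ep, n_iterations = 2, k_folds = 5, seed_base = 3)
  b <- pairwise_cv(ep, n_iterations = 2, k_folds = 5, seed_base = 3)
  expect_identical(a$accuracy, b$accuracy)
  d <- pairwise_cv(ep, n_iterations = 2, k_folds = 5, seed_base = 4)
  expect_false(identical(a$accuracy, d$accuracy))

  # swapping the class labels leaves accuracy unchanged
  ep2 <- ep
  attr(ep2, "labels") <- ifelse(attr(ep, "labels") == "a", "b", "a")
  c2 <- pairwise_cv(ep2, n_iterations = 2, k_folds = 5, seed_base = 3)
  expect_equal(a$accuracy, c2$accuracy)
})

test_that("uninformative features stay inside the chance band", {
  # null: no class signal; peak of 10 time steps stays below the
  # max-selection-adjusted binomial band around 50%
  ep <- toy_epochs(n_per_class = 50, shift = 0, n_time = 12, seed = 22)
  cv <- pairwise_cv(ep, n_iterations = 3, k_folds = 5,
                    time_window_s = c(0, 2.5))
  expect_lt(cv$peak_accuracy_mean, 62)
  expect_gt(cv$peak_accuracy_mean, 38)

  # informative electrodes removed -> accuracy collapses to chance band
  ep2 <- toy_epochs(n_per_class = 25, shift = 3, informative = 1:2,
                    seed = 23)
  cv_all <- pairwise_cv(ep2, n_iterations = 2, k_folds = 5)
  cv_rest <- pairwise_cv(ep2, roi = 3:6, n_iterations = 2, k_folds = 5)
  expect_gt(cv_all$peak_accuracy_mean, 90)
  expect_lt(cv_rest$peak_accuracy_mean, 70)
})

test_that("CV input contracts are enforced", {
  ep <- toy_epochs(n_per_class = 6)
  expect_error(pairwise_cv(ep, k_folds = 10), "at least k_folds")
  ep3 <- toy_epochs(n_per_class = 8)
  attr(ep3, "labels")[1:4] <- "c"
  expect_error(pairwise_cv(ep3, k_folds = 2), "classes")
})

test_that("permutation p-values behave like the fitted Gaussian tail", {
  ep <- toy_epochs(n_per_class = 10, shift = 2.5, seed = 24)
  cv <- pairwise_cv(ep, n_iterations = 2, k_folds = 5)
  pt <- permutation_pvalue(ep, cv, n_permutations = 30, seed = 5)
  expect_gt(pt$p_value, 0)
  expect_lt(pt$p_value, 1)
  expect_lt(pt$p_value, 0.05)   # real effect detected
  expect_equal(length(pt$null_performances), 30)

  # observed equal to the null mean -> p = 0.5 (Gaussian symmetry)
  cv_mid <- cv
  cv_mid$peak_accuracy_mean <- pt$null_mean
  pt_mid <- permutation_pvalue(ep, cv_mid, n_permutations = 30, seed = 5)
  expect_equal(pt_mid$p_value, 0.5, tolerance = 1e-9)

  # identical seeds reproduce the null exactly
  pt2 <- permutation_pvalue(ep, cv, n_permutations = 30, seed = 5)
  expect_identical(pt$null_performances, pt2$null_performances)

  expect_warning(permutation_pvalue(ep, cv, n_permutations = 5, seed = 1),
                 "20 permutations")
})

test_that("null permutation performances center at chance", {
  ep <- toy_epochs(n_per_class = 15, shift = 0, seed = 25, n_time = 8)
  cv <- pairwise_cv(ep, n_iterations = 2, k_folds = 5,
                    time_window_s = c(0, 1.5))
  pt <- permutation_pvalue(ep, cv, n_permutations = 25, seed = 6,
                           null_statistic = "observed_peak")
  se <- pt$null_sd / sqrt(length(pt$null_performances))
  expect_lt(abs(pt$null_mean - 50), max(2 * se, 5))
})

test_that("Benjamini-Hochberg adjustment matches the hand step-up", {
  # hand-computed: m=4, p=(0.01,0.02,0.03,0.04) -> all 0.04
  expect_equal(bh_correct(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_correct(0.37), 0.37)            # m = 1 unchanged
  expect_equal(bh_correct(rep(1, 5)), rep(1, 5))  # upper bound

  # brute-force step-up with monotone flooring on random instances
  brute_bh <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
    out <- numeric(m)
    out[o] <- pmin(adj, 1)
    out
  }
  for (seed in 1:10) {
    set.seed(seed)
    p <- runif(sample(3:12, 1))
    expect_equal(bh_correct(p), brute_bh(p), tolerance = 1e-12)
  }
  expect_error(bh_correct(numeric(0)), "empty")
  expect_error(bh_correct(c(0.1, 1.2)), "0, 1")
})

test_that("signed-rank subset comparison matches the normal-approx oracle", {
  expect_error(subset_comparison(c(1, 2, 3), c(1, 2, 3)), "degenerate")
  expect_error(subset_comparison(1:3, 1:4), "paired")

  # constant shift of 5 at n=50: decisive, median difference 5
  set.seed(26)
  full <- rnorm(50, 70, 5)
  res <- subset_comparison(full, full - 5)
  expect_lt(res$p_value, 0.001)
  expect_equal(res$median_diff, 5)

  # oracle: signed-rank statistic + continuity-corrected normal tail
  oracle_p <- function(x, y) {
    d <- x - y
    d <- d[d != 0]
    n <- length(d)
    W <- sum(rank(abs(d))[d > 0])
    mu <- n * (n + 1) / 4
    sg <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
    z <- (W - mu - sign(W - mu) * 0.5) / sg
    2 * min(pnorm(z), pnorm(z, lower.tail = FALSE))
  }
  for (seed in 1:8) {
    set.seed(seed)
    x <- rnorm(30, 65, 6)
    y <- x - rnorm(30, 1, 4)
    res <- subset_comparison(x, y)
    expect_equal(res$p_value, oracle_p(x, y), tolerance = 1e-9)
  }
})

test_that("all-pairs decoding enumerates every unordered class pair", {
  set.seed(27)
  nt <- 5 * 6
  arr <- array(rnorm(nt * 4 * 6), c(nt, 4, 6))
  ep <- structure(arr,
                  labels = rep(c("thumb", "index", "middle", "ring",
                                 "little"), each = 6),
                  time_s = (0:5) / 4, feature_fs = 4,
                  channel_labels = sprintf("CH%d", 1:4), band = c(8, 12),
                  class = "uhd_epochs")
  res <- all_pairwise_cv(ep, n_iterations = 1, k_folds = 2,
                         time_window_s = c(0, 1))
  expect_equal(nrow(res$table), 10)
  expect_equal(anyDuplicated(res$table$pair), 0)
})
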