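# Time-resolved pairwise linear-SVM decoding with repeated stratified
# k-fold cross-validation, permutation-based empirical p-values with a
# Gaussian null fit, Benjamini-Hochberg correction, and electrode-subset
# comparison.

# Stratified fold assignment: within each class, indices are shuffled and
# folds dealt cyclically.
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      if (length(idx) < k)
        stop("class '", cl, "' has fewer trials (", length(idx),
             ") than folds (", k, ")")
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# Linear SVM (unit box constraint, standardized features) predictions for
# one train/test split. Standardization uses training statistics;
# zero-variance features pass through unscaled.
svm_fold_predict <- function(Xtr, ytr, Xte) {
  mu <- colMeans(Xtr)
  sdv <- apply(Xtr, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Xtr <- sweep(sweep(Xtr, 2, mu), 2, sdv, "/")
  Xte <- sweep(sweep(Xte, 2, mu), 2, sdv, "/")
  fit <- e1071::svm(Xtr, factor(ytr), kernel = "linear", cost = 1,
                    scale = FALSE, fitted = FALSE)
  # linear-kernel decision values computed directly (equivalent to
  # predict(fit, Xte), without the dispatch overhead)
  w <- crossprod(fit$SV, fit$coefs)
  dv <- as.numeric(Xte %*% w) - fit$rho
  lv <- fit$levels[fit$labels]
  ifelse(dv > 0, lv[1], lv[2])
}

# Core n-times k-fold CV over the given time-step indices. Returns the
# iterations x steps mean fold accuracy (percent) and per-class accuracy
# arrays.
cv_accuracy_matrix <- function(epochs, trials, y, roi, steps,
                               n_iterations, k_folds, seed_base,
                               per_class = FALSE) {
  classes <- sort(unique(y))
  acc <- matrix(0, n_iterations, length(steps))
  acc_cl <- if (per_class)
    array(0, dim = c(n_iterations, length(steps), length(classes)))
  for (it in seq_len(n_iterations)) {
    fold <- stratified_folds(y, k_folds, seed_base + it - 1L)
    for (si in seq_along(steps)) {
      s <- steps[si]
      X <- epochs[trials, roi, s, drop = FALSE]
      dim(X) <- c(length(trials), length(roi))
      fa <- numeric(k_folds)
      pred_all <- character(length(y))
      for (f in seq_len(k_folds)) {
        te <- fold == f
        pred <- svm_fold_predict(X[!te, , drop = FALSE], y[!te],
                                 X[te, , drop = FALSE])
        pred_all[te] <- pred
        fa[f] <- mean(pred == y[te])
      }
      acc[it, si] <- 100 * mean(fa)
      if (per_class)
        for (ci in seq_along(classes))
          acc_cl[it, si, ci] <-
            100 * mean(pred_all[y == classes[ci]] == classes[ci])
    }
  }
  if (per_class) list(acc = acc, acc_class = acc_cl, classes = classes)
  else list(acc = acc)
}

#' Time-resolved pairwise cross-validated decoding
#'
#' For each feature time step in the task window, the two classes' trials
#' are classified from the ROI channels' band-power features with a linear
#' SVM (unit box constraint, features standardized per training fold) in a
#' stratified k-fold CV repeated `n_iterations` times; the fold assignment
#' of iteration i is seeded with `seed_base + i - 1`, so results are
#' reproducible. Model performance is the mean accuracy over iterations at
#' the time step where that mean is highest (earliest such step on ties).
#'
#' @param epochs `uhd_epochs` (typically both bands combined via
#'   [combine_bands()]).
#' @param pair character vector of the two class labels; defaults to the
#'   two labels present.
#' @param roi logical mask or integer indices of epoch channels to use
#'   (default all).
#' @param time_window_s classified time window relative to cue; steps with
#'   `start <= t < end` are used (default `c(0, 5)`, 20 steps at 4 Hz).
#' @param n_iterations,k_folds CV repetitions and folds (defaults 10, 10).
#' @param seed_base base fold seed (default 1: iteration seeds 1..n).
#' @return object of class `uhd_cv`: list with `accuracy` (iterations x
#'   steps, percent), `time_s` (step times), `peak_time_s`, `peak_step`,
#'   `peak_accuracy_mean`, `peak_accuracy_sd`, `pair`, `n_trials`, `seeds`.
#' @export
pairwise_cv <- function(epochs, pair = NULL, roi = NULL,
                        time_window_s = c(0, 5), n_iterations = 10,
                        k_folds = 10, seed_base = 1) {
  stopifnot(inherits(epochs, "uhd_epochs"))
  labs <- attr(epochs, "labels")
  if (is.null(pair)) {
    pair <- unique(labs)
    if (length(pair) != 2L)
      stop("epochs contain ", length(pair),
           " classes; supply 'pair' to select two")
  }
  trials <- which(labs %in% pair)
  y <- labs[trials]
  if (length(unique(y)) != 2L) stop("both classes must be present")
  if (min(table(y)) < k_folds)
    stop("each class needs at least k_folds trials for stratified CV")
  nch <- dim(epochs)[2]
  roi <- if (is.null(roi)) seq_len(nch)
  else if (is.logical(roi)) which(roi) else as.integer(roi)
  tt <- attr(epochs, "time_s")
  steps <- which(tt >= time_window_s[1] & tt < time_window_s[2])
  if (length(steps) == 0L) stop("no time steps in the task window")

  cvres <- cv_accuracy_matrix(epochs, trials, y, roi, steps,
                              n_iterations, k_folds, seed_base,
                              per_class = TRUE)
  acc <- cvres$acc
  m <- colMeans(acc)
  peak <- which.max(m)          # earliest maximum
  structure(list(accuracy = acc, accuracy_per_class = cvres$acc_class,
                 classes = cvres$classes, time_s = tt[steps],
                 peak_time_s = tt[steps[peak]], peak_step = steps[peak],
                 peak_accuracy_mean = m[peak],
                 peak_accuracy_sd = stats::sd(acc[, peak]),
                 pair = pair, n_trials = length(trials),
                 roi = roi, time_window_s = time_window_s,
                 n_iterations = n_iterations, k_folds = k_folds,
                 seeds = seed_base + seq_len(n_iterations) - 1L),
            class = "uhd_cv")
}

#' @export
print.uhd_cv <- function(x, ...) {
  cat(sprintf("pairwise CV [%s vs %s]: peak %.1f (%.1f)%% at %.2f s (%dx%d-fold, %d trials)\n",
              x$pair[1], x$pair[2], x$peak_accuracy_mean,
              x$peak_accuracy_sd, x$peak_time_s, x$n_iterations,
              x$k_folds, x$n_trials))
  invisible(x)
}

#' @export
summary.uhd_cv <- function(object, ...) {
  data.frame(pair = paste(object$pair, collapse = " vs "),
             peak_time_s = object$peak_time_s,
             acc_mean = object$peak_accuracy_mean,
             acc_sd = object$peak_accuracy_sd,
             n_trials = object$n_trials)
}

#' Permutation-based empirical p-value of a decoding result
#'
#' The class labels are permuted `n_permutations` times; each permutation's
#' null model performance is estimated with the same repeated stratified CV
#' as the observed model (each permutation uses fresh fold seeds derived
#' from `seed` and the permutation index). A normal distribution is fitted
#' to the null performances and the p-value is the upper-tail probability
#' of the observed peak accuracy (so values below 1/`n_permutations` are
#' attainable).
#'
#' By default each null model's performance is its own peak accuracy over
#' the task-window time steps -- the same max-over-time statistic as the
#' observed performance, which keeps null p-values uniform; alternatively
#' the null models can be evaluated at the observed peak step only.
#'
#' @param epochs,pair,roi as in [pairwise_cv()].
#' @param observed `uhd_cv` result for the unpermuted labels.
#' @param n_permutations number of label permutations (default 100).
#' @param seed integer seed.
#' @param null_statistic `"own_peak"` (default) or `"observed_peak"`.
#' @param n_iterations,k_folds CV shape for null models (defaults: as in
#'   `observed`).
#' @return object of class `uhd_perm`: list with `null_performances`,
#'   `null_mean`, `null_sd`, `p_value`, `observed`.
#' @export
permutation_pvalue <- function(epochs, observed, pair = NULL, roi = NULL,
                               n_permutations = 100, seed = 1,
                               null_statistic = c("own_peak",
                                                  "observed_peak"),
                               n_iterations = NULL, k_folds = NULL) {
  stopifnot(inherits(observed, "uhd_cv"))
  null_statistic <- match.arg(null_statistic)
  if (n_permutations < 20)
    warning("fewer than 20 permutations: unstable Gaussian null fit")
  if (is.null(pair)) pair <- observed$pair
  if (is.null(roi)) roi <- observed$roi
  if (is.null(n_iterations)) n_iterations <- observed$n_iterations
  if (is.null(k_folds)) k_folds <- observed$k_folds
  labs <- attr(epochs, "labels")
  trials <- which(labs %in% pair)
  y <- labs[trials]
  roi <- if (is.logical(roi)) which(roi) else as.integer(roi)
  tt <- attr(epochs, "time_s")
  steps <- if (null_statistic == "own_peak")
    which(tt >= observed$time_window_s[1] & tt < observed$time_window_s[2])
  else observed$peak_step

  perf <- numeric(n_permutations)
  for (pm in seq_len(n_permutations)) {
    ps <- (seed * 10007 + pm * 7919) %% 2147483647
    yp <- with_seed(ps, sample(y))
    acc <- cv_accuracy_matrix(epochs, trials, yp, roi, steps,
                              n_iterations, k_folds,
                              seed_base = ps + 1)$acc
    perf[pm] <- max(colMeans(acc))
  }
  m <- mean(perf); s <- stats::sd(perf)
  p <- stats::pnorm(observed$peak_accuracy_mean, m, s, lower.tail = FALSE)
  p <- min(max(p, .Machine$double.xmin), 1 - .Machine$double.eps)
  structure(list(null_performances = perf, null_mean = m, null_sd = s,
                 p_value = p, observed = observed$peak_accuracy_mean,
                 null_statistic = null_statistic),
            class = "uhd_perm")
}

#' @export
print.uhd_perm <- function(x, ...) {
  cat(sprintf("permutation test: observed %.1f%%, null %.1f (%.1f)%% [%d perms], p = %.4g\n",
              x$observed, x$null_mean, x$null_sd,
              length(x$null_performances), x$p_value))
  invisible(x)
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Standard step-up adjustment with monotonicity enforcement, applied per
#' batch of pairwise tests.
#'
#' @param p_values numeric vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
bh_correct <- function(p_values) {
  if (length(p_values) == 0L) stop("empty p-value list")
  if (any(!is.finite(p_values) | p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Compare paired model performances between electrode densities
#'
#' Two-tailed Wilcoxon signed-rank test on paired performance vectors
#' (e.g. full uHD montage vs a density subset), with the median and
#' nearest-rank IQR of the paired differences.
#'
#' @param performances_full,performances_subset paired numeric vectors.
#' @return list with `statistic`, `p_value`, `median_diff`, `iqr_diff`
#'   (25th/75th percentiles of the differences).
#' @export
subset_comparison <- function(performances_full, performances_subset) {
  if (length(performances_full) != length(performances_subset))
    stop("performance vectors must be paired (equal length)")
  d <- performances_full - performances_subset
  if (all(d == 0)) stop("all paired differences are zero; degenerate test")
  wt <- stats::wilcox.test(performances_full, performances_subset,
                           paired = TRUE, alternative = "two.sided",
                           exact = FALSE, correct = TRUE)
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       median_diff = stats::median(d),
       iqr_diff = c(quantile_nearest_rank(d, 0.25),
                    quantile_nearest_rank(d, 0.75)))
}

#' All pairwise decoding problems of a study
#'
#' Runs [pairwise_cv()] for every unordered pair of classes and applies
#' Benjamini-Hochberg correction to the permutation p-values when
#' `n_permutations > 0`.
#'
#' @param epochs `uhd_epochs` with all classes.
#' @param roi,time_window_s,n_iterations,k_folds,seed_base as in
#'   [pairwise_cv()].
#' @param n_permutations permutations per pair (0 to skip inference).
#' @param perm_seed seed for the permutation null.
#' @return list with `results` (list of `uhd_cv`), `table` (data frame:
#'   pair, peak_time_s, acc_mean, acc_sd, p_raw, p_fdr).
#' @export
all_pairwise_cv <- function(epochs, roi = NULL, time_window_s = c(0, 5),
                            n_iterations = 10, k_folds = 10,
                            seed_base = 1, n_permutations = 0,
                            perm_seed = 1) {
  classes <- sort(unique(attr(epochs, "labels")))
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  res <- vector("list", length(pairs))
  tab <- NULL
  for (i in seq_along(pairs)) {
    cv <- pairwise_cv(epochs, pair = pairs[[i]], roi = roi,
                      time_window_s = time_window_s,
                      n_iterations = n_iterations, k_folds = k_folds,
                      seed_base = seed_base)
    p_raw <- NA_real_
    if (n_permutations > 0) {
      pt <- permutation_pvalue(epochs, cv, n_permutations = n_permutations,
                               seed = perm_seed + i)
      cv$permutation <- pt
      p_raw <- pt$p_value
    }
    res[[i]] <- cv
    tab <- rbind(tab, data.frame(
      pair = paste(pairs[[i]], collapse = "_vs_"),
      peak_time_s = cv$peak_time_s, acc_mean = cv$peak_accuracy_mean,
      acc_sd = cv$peak_accuracy_sd, p_raw = p_raw,
      stringsAsFactors = FALSE))
  }
  tab$p_fdr <- if (n_permutations > 0) bh_correct(tab$p_raw) else NA_real_
  list(results = res, table = tab)
}
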