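# Internal numerical helpers shared across pipeline stages.

#' Evaluate an expression with a temporarily seeded RNG
#'
#' Saves and restores `.Random.seed` so that seeded pipeline stages do not
#' disturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Causal (forward-only) application of an IIR filter to the rows of a
# channels x samples matrix.
filter_rows <- function(b, a, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  out <- x
  for (i in seq_len(nrow(x)))
    out[i, ] <- as.numeric(signal::filter(b, a, x[i, ]))
  out
}

# 4th-order Butterworth band-pass design (the band transform doubles the
# polynomial order), applied causally.
bandpass_rows <- function(x, band, fs) {
  ny <- fs / 2
  if (!(band[1] > 0 && band[1] < band[2] && band[2] < ny))
    stop("band must satisfy 0 < low < high < Nyquist (", ny, " Hz)")
  bf <- signal::butter(4, band / ny, type = "pass")
  filter_rows(bf$b, bf$a, x)
}

# Zero-phase FIR low-pass with reflection padding (suppresses edge
# transients of plain filtering).
fir_lowpass_zerophase <- function(x, h) {
  n <- length(x)
  pad <- min(n - 1L, 3L * length(h))
  xp <- c(2 * x[1] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  y <- as.numeric(signal::filtfilt(as.numeric(h), 1, xp))
  y[(pad + 1L):(pad + n)]
}

# Polyphase rational resampler for one signal: zero-stuff by p, FIR low-pass
# at 0.9 / max(p, q) of Nyquist, zero-phase, take every q-th sample.
resample_signal <- function(x, p, q) {
  g <- function(a, b) if (b == 0) a else Recall(b, a %% b)
  d <- g(p, q); p <- p %/% d; q <- q %/% d
  if (p > 1L) {
    up <- numeric(length(x) * p)
    up[seq(1L, length(up), by = p)] <- x * p
    x <- up
  }
  h <- signal::fir1(20L * max(p, q), 0.9 / max(p, q))
  y <- fir_lowpass_zerophase(x, h)
  y[seq(1L, length(y), by = q)]
}

# Centered moving average with shrinking (partial) windows at the edges.
# width must be odd.
moving_average_centered <- function(x, width) {
  stopifnot(width %% 2L == 1L)
  half <- (width - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Nearest-rank (inverse empirical CDF, type 1) quantile.
quantile_nearest_rank <- function(x, p) {
  s <- sort(x)
  s[max(1L, ceiling(p * length(s)))]
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop(sprintf("'%s' must be a finite scalar in [%s, %s]", name, lower, upper))
  x
}
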