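# Redundancy analysis between neighboring electrodes: distance, Pearson
# correlation and coefficient of determination over the 1-30 Hz band.

#' Neighboring-electrode correlation statistics
#'
#' Band-pass filters the preprocessed recording (1-30 Hz by default, the
#' frequency components typically analysed in EEG experiments) and
#' computes, for every unique neighbor pair of the graph, the Pearson
#' correlation r and R^2 = r^2 over all samples, together with
#' median/nearest-rank-IQR summaries.
#'
#' @param rec preprocessed (post-CAR) `uhd_recording`; channel indices must
#'   match the montage the graph was built from.
#' @param graph `uhd_neighbor_graph`.
#' @param band band-pass corner frequencies in Hz (default `c(1, 30)`).
#' @return object of class `uhd_neighbor_stats`: list with `pairs` (data
#'   frame: i, j, distance_mm, r, r_squared) and `summary` (data frame:
#'   metric, median, q25, q75).
#' @export
neighbor_correlations <- function(rec, graph, band = c(1, 30)) {
  stopifnot(inherits(rec, "uhd_recording"),
            inherits(graph, "uhd_neighbor_graph"))
  if (max(graph$i, graph$j) > nrow(rec$data))
    stop("graph refers to channels beyond the recording")
  x <- bandpass_rows(rec$data, band, rec$fs)
  sds <- apply(x, 1, stats::sd)
  ok <- sds[graph$i] > 0 & sds[graph$j] > 0
  if (any(!ok))
    warning(sum(!ok), " pair(s) dropped: constant channel")
  g <- graph[ok, , drop = FALSE]
  r <- vapply(seq_len(nrow(g)), function(k)
    stats::cor(x[g$i[k], ], x[g$j[k], ]), 0)
  pairs <- data.frame(i = g$i, j = g$j, distance_mm = g$distance_mm,
                      r = r, r_squared = r^2)
  summ <- do.call(rbind, lapply(
    c("distance_mm", "r", "r_squared"),
    function(mt) data.frame(
      metric = mt,
      median = stats::median(pairs[[mt]]),
      q25 = quantile_nearest_rank(pairs[[mt]], 0.25),
      q75 = quantile_nearest_rank(pairs[[mt]], 0.75))))
  structure(list(pairs = pairs, summary = summ, band = band),
            class = "uhd_neighbor_stats")
}

#' @export
print.uhd_neighbor_stats <- function(x, ...) {
  s <- x$summary
  for (k in seq_len(nrow(s)))
    cat(sprintf("  %-12s median %.3g [%.3g; %.3g]\n", s$metric[k],
                s$median[k], s$q25[k], s$q75[k]))
  invisible(x)
}
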