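# Recording container and plain-format I/O (EDF, BIDS-style events.tsv).

#' Construct a multichannel EEG recording
#'
#' The pipeline's flowing object: a channels x samples matrix in microvolts
#' with its sampling rate, channel labels, and event table.
#'
#' @param data numeric matrix, channels x samples (microvolts).
#' @param fs sampling frequency in Hz.
#' @param labels character vector of channel labels (length `nrow(data)`).
#' @param events data frame with columns `onset` (s), `duration` (s),
#'   `trial_type`.
#' @return object of class `uhd_recording`.
#' @export
recording <- function(data, fs, labels = NULL, events = NULL) {
  data <- as.matrix(data)
  check_scalar(fs, "fs", lower = 1e-9)
  if (is.null(labels)) labels <- sprintf("CH%03d", seq_len(nrow(data)))
  if (length(labels) != nrow(data))
    stop("labels length must match number of channels")
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  if (is.null(events))
    events <- data.frame(onset = numeric(0), duration = numeric(0),
                         trial_type = character(0))
  dur <- ncol(data) / fs
  if (nrow(events) && any(events$onset < 0 | events$onset > dur))
    stop("all event onsets must lie within the recording duration")
  structure(list(data = data, fs = fs, labels = labels, events = events),
            class = "uhd_recording")
}

#' @export
print.uhd_recording <- function(x, ...) {
  cat(sprintf("uHD recording: %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              nrow(x$events)))
  invisible(x)
}

pad_ascii <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to a European Data Format (EDF) file
#'
#' Minimal 16-bit EDF writer: one data record per second, all channels at
#' the recording's sampling rate, physical range set per channel from the
#' data (symmetric). The final partial second is zero-padded.
#'
#' @param rec `uhd_recording`.
#' @param path output file path.
#' @param phys_max optional fixed symmetric physical range (microvolts); by
#'   default the per-channel absolute maximum.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, phys_max = NULL) {
  stopifnot(inherits(rec, "uhd_recording"))
  if (rec$fs != round(rec$fs))
    stop("EDF writer requires an integer sampling rate")
  nch <- nrow(rec$data)
  fs <- as.integer(rec$fs)
  nrec <- as.integer(ceiling(ncol(rec$data) / fs))
  pm <- if (is.null(phys_max)) pmax(apply(abs(rec$data), 1, max), 1e-6)
  else rep(phys_max, nch)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_ascii("0", 8), pad_ascii("X", 80), pad_ascii("uhdfinger", 80),
    pad_ascii("01.01.00", 8), pad_ascii("00.00.00", 8),
    pad_ascii(256L * (1L + nch), 8), pad_ascii("", 44),
    pad_ascii(nrec, 8), pad_ascii("1", 8), pad_ascii(nch, 4),
    paste(pad_ascii(rec$labels, 16), collapse = ""),
    paste(rep(pad_ascii("", 80), nch), collapse = ""),
    paste(rep(pad_ascii("uV", 8), nch), collapse = ""),
    paste(pad_ascii(formatC(-pm, digits = 6, format = "g"), 8), collapse = ""),
    paste(pad_ascii(formatC(pm, digits = 6, format = "g"), 8), collapse = ""),
    paste(rep(pad_ascii("-32768", 8), nch), collapse = ""),
    paste(rep(pad_ascii("32767", 8), nch), collapse = ""),
    paste(rep(pad_ascii("", 80), nch), collapse = ""),
    paste(rep(pad_ascii(fs, 8), nch), collapse = ""),
    paste(rep(pad_ascii("", 32), nch), collapse = ""))
  writeChar(hdr, con, eos = NULL)

  x <- rec$data
  if (ncol(x) < nrec * fs)
    x <- cbind(x, matrix(0, nch, nrec * fs - ncol(x)))
  scale <- 32767 / pm
  for (r in seq_len(nrec)) {
    seg <- x[, ((r - 1L) * fs + 1L):(r * fs), drop = FALSE]
    dig <- round(seg * scale)                # channels x fs
    dig <- pmax(pmin(dig, 32767), -32768)
    writeBin(as.integer(t(dig)), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' Supports the common EDF layout with equal sampling rate across channels
#' and 1 s data records.
#'
#' @param path EDF file path.
#' @param events optional event table to attach.
#' @return `uhd_recording`.
#' @export
read_edf <- function(path, events = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                  # header bytes
  rd(44)
  nrec <- as.integer(rd(8))
  recdur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  labels <- vapply(seq_len(nch), function(i) rd(16), "")
  for (i in seq_len(nch)) rd(80)         # transducer
  for (i in seq_len(nch)) rd(8)          # phys dim
  pmin_ <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  for (i in seq_len(nch)) rd(80)         # prefiltering
  spr <- as.integer(vapply(seq_len(nch), function(i) rd(8), ""))
  for (i in seq_len(nch)) rd(32)
  if (length(unique(spr)) != 1L)
    stop("read_edf supports a single sampling rate across channels")
  fs <- spr[1] / recdur
  out <- matrix(0, nch, nrec * spr[1])
  for (r in seq_len(nrec)) {
    raw <- readBin(con, integer(), n = nch * spr[1], size = 2L,
                   endian = "little")
    seg <- matrix(raw, nrow = spr[1], ncol = nch)   # samples x channels
    idx <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
    out[, idx] <- t(seg)
  }
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  out <- out * gain + (pmax_ + pmin_) / 2
  recording(out, fs, labels, events)
}

#' Write / read a BIDS-style events table
#'
#' Tab-separated columns `onset`, `duration`, `trial_type` (one extra `run`
#' column is kept when present).
#'
#' @param events data frame.
#' @param path file path.
#' @return `write_events` returns `path` invisibly; `read_events` the table.
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
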