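#' Minimal European Data Format (EDF) writer
#'
#' Writes a continuous multichannel recording as a plain EDF file
#' (16-bit samples, one-second data records).  Only the features needed
#' for round-tripping synthetic recordings are implemented: a single
#' continuous segment, identical sampling rate across channels, and
#' per-channel physical scaling derived from the data range.
#'
#' @param signals numeric matrix, samples x channels (microvolts).
#' @param sample_rate sampling rate in Hz (integer, samples per record).
#' @param path output file path.
#' @param labels optional channel labels (<= 16 ASCII chars each).
#' @return `path`, invisibly.
#' @export
write_edf <- function(signals, sample_rate, path, labels = NULL) {
  if (!is.matrix(signals)) signals <- matrix(signals, ncol = 1)
  ns <- ncol(signals)
  fs <- as.integer(round(sample_rate))
  if (fs <= 0) stop_invalid("sample_rate must be positive")
  labels <- labels %||% colnames(signals) %||% sprintf("ch%03d", seq_len(ns))
  n <- nrow(signals)
  n_rec <- ceiling(n / fs)
  if (n %% fs != 0)  # pad the final record with the last sample value
    signals <- rbind(signals,
                     signals[rep(n, n_rec * fs - n), , drop = FALSE])

  pmin <- apply(signals, 2, min)
  pmax <- apply(signals, 2, max)
  flat <- pmax - pmin < .Machine$double.eps
  pmin[flat] <- pmin[flat] - 1; pmax[flat] <- pmax[flat] + 1
  dmin <- -32768; dmax <- 32767

  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8), pad("X X X X", 80), pad("Startdate 01-JAN-2000", 80),
    pad("01.01.00", 8), pad("00.00.00", 8),
    pad(256 + ns * 256, 8), pad("", 44), pad(n_rec, 8), pad(1, 8), pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fmt8 <- function(x) {          # numeric field, at most 8 ASCII chars
    vapply(x, function(v) {
      for (d in 7:1) {
        s <- formatC(v, format = "g", digits = d)
        if (nchar(s) <= 8) return(formatC(s, width = 8, flag = "-"))
      }
      formatC(s, width = 8, flag = "-")
    }, character(1))
  }
  sig_hdr <- paste0(
    paste(pad(substr(labels, 1, 16), 16), collapse = ""),
    paste(rep(pad("", 80), ns), collapse = ""),
    paste(rep(pad("uV", 8), ns), collapse = ""),
    paste(fmt8(pmin), collapse = ""), paste(fmt8(pmax), collapse = ""),
    paste(rep(pad(dmin, 8), ns), collapse = ""),
    paste(rep(pad(dmax, 8), ns), collapse = ""),
    paste(rep(pad("", 80), ns), collapse = ""),
    paste(rep(pad(fs, 8), ns), collapse = ""),
    paste(rep(pad("", 32), ns), collapse = ""))
  writeChar(sig_hdr, con, eos = NULL)

  scale <- (dmax - dmin) / (pmax - pmin)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    block <- vapply(seq_len(ns), function(j) {
      as.integer(round((signals[idx, j] - pmin[j]) * scale[j]) + dmin)
    }, integer(fs))
    writeBin(as.vector(block), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Minimal EDF reader
#'
#' Reads continuous EDF files written by [write_edf()] (or any plain EDF
#' with a uniform sampling rate across channels).
#'
#' @param path EDF file path.
#' @return list with `signals` (samples x channels matrix, physical
#'   units), `sample_rate` (Hz), and `labels`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  labels <- fld(16); fld(80); fld(8)
  pmin <- as.numeric(fld(8)); pmax <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8))
  fld(32)
  if (length(unique(spr)) != 1)
    ecog_error("ecog_schema_error", "channels differ in samples per record")
  raw <- readBin(con, integer(), n = n_rec * sum(spr), size = 2,
                 endian = "little")
  dim(raw) <- c(spr[1], ns, n_rec)
  signals <- matrix(0, n_rec * spr[1], ns)
  scale <- (pmax - pmin) / (dmax - dmin)
  for (j in seq_len(ns))
    signals[, j] <- (as.vector(raw[, j, ]) - dmin[j]) * scale[j] + pmin[j]
  colnames(signals) <- labels
  list(signals = signals, sample_rate = spr[1] / rec_dur, labels = labels)
}
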