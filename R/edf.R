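# Minimal European Data Format (EDF) support: continuous recordings,
# 16-bit samples, one fixed sampling rate per signal.  Covers what this
# package writes and reads back; it is not a general EDF(+) library.

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = -width, flag = " ")
}

#' Write a recording as an EDF file
#'
#' Samples are quantized to 16-bit integers over each channel's observed
#' physical range, so a write/read round trip is exact only up to EDF
#' quantization.  The recording is truncated to a whole number of data
#' records.
#'
#' @param rec an [recording()].
#' @param path output path.
#' @param record_duration data-record length in seconds; `fs *
#'   record_duration` must be an integer.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, record_duration = 1) {
  ns <- length(rec$channels)
  spr <- rec$fs * record_duration
  if (abs(spr - round(spr)) > 1e-9) {
    stop("fs * record_duration must be an integer", call. = FALSE)
  }
  spr <- as.integer(round(spr))
  n_rec <- n_samples(rec) %/% spr
  if (n_rec < 1L) stop("recording shorter than one data record",
                       call. = FALSE)
  phys_min <- phys_max <- numeric(ns)
  dig <- matrix(0L, nrow = spr * n_rec, ncol = ns)
  for (i in seq_len(ns)) {
    x <- rec$channels[[i]][seq_len(spr * n_rec)]
    lim <- max(abs(range(x)), 1e-12)
    phys_min[i] <- -lim; phys_max[i] <- lim
    dig[, i] <- as.integer(round(x / lim * 32767))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8), pad_field("X", 80), pad_field("sleeparch", 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 * (1 + ns), 8), pad_field("", 44),
    pad_field(n_rec, 8), pad_field(format(record_duration), 8),
    pad_field(ns, 4),
    paste(pad_field(names(rec$channels), 16), collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),
    paste(rep(pad_field("uV", 8), ns), collapse = ""),
    paste(pad_field(format(phys_min, digits = 6), 8), collapse = ""),
    paste(pad_field(format(phys_max, digits = 6), 8), collapse = ""),
    paste(rep(pad_field("-32768", 8), ns), collapse = ""),
    paste(rep(pad_field("32767", 8), ns), collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),
    paste(rep(pad_field(spr, 8), ns), collapse = ""),
    paste(rep(pad_field("", 32), ns), collapse = "")
  )
  writeChar(hdr, con, eos = NULL)
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1L) * spr + 1L):(r * spr)
    for (i in seq_len(ns)) {
      writeBin(dig[rows, i], con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()] (or any continuous EDF
#' with one sampling rate across signals)
#'
#' @param path file path.
#' @param zt_start ZT of the first sample, seconds.
#' @return an [recording()].
#' @export
read_edf <- function(path, zt_start = 0) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) {
    out <- suppressWarnings(readChar(con, n, useBytes = TRUE))
    if (length(out) == 0L || nchar(out, type = "bytes") < n) {
      stop("corrupt EDF header: truncated file", call. = FALSE)
    }
    trimws(out)
  }
  version <- rd(8)
  if (version != "0") stop("corrupt EDF header: bad version field",
                           call. = FALSE)
  rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes (recomputed below)
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(n_rec) || is.na(ns) || ns < 1L) {
    stop("corrupt EDF header: bad record/signal counts", call. = FALSE)
  }
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)           # transducer
  for (i in seq_len(ns)) rd(8)            # physical dimension
  phys_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  phys_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dig_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dig_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)           # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)           # reserved
  chans <- lapply(seq_len(ns), function(i) numeric(spr[i] * n_rec))
  names(chans) <- labels
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      raw <- readBin(con, integer(), n = spr[i], size = 2L,
                     endian = "little")
      scale <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
      chans[[i]][((r - 1L) * spr[i] + 1L):(r * spr[i])] <-
        phys_min[i] + (raw - dig_min[i]) * scale
    }
  }
  fs <- spr[1] / rec_dur
  recording(chans, fs = fs, zt_start = zt_start)
}
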