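#' Construct a polysomnographic recording
#'
#' Container for a multichannel EEG/EMG recording.  Channel roles follow
#' the two-EEG + nuchal-EMG montage used for rodent polysomnography:
#' `EEG_rostral`, `EEG_caudal`, `EMG`.  Amplitudes are in arbitrary
#' (voltage-like) units.
#'
#' @param channels named list of equal-length numeric vectors; names are
#'   channel roles.
#' @param fs sampling rate in Hz.
#' @param zt_start Zeitgeber time of the first sample, seconds.
#' @return object of class `eeg_recording`.
#' @export
recording <- function(channels, fs, zt_start = 0) {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels)))) {
    stop("channels must be a named list of numeric vectors", call. = FALSE)
  }
  lens <- vapply(channels, length, integer(1))
  if (length(unique(lens)) != 1L) {
    stop("all channels must have equal length", call. = FALSE)
  }
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive", call. = FALSE)
  structure(
    list(channels = lapply(channels, as.numeric), fs = fs,
         zt_start = zt_start),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  n <- length(x$channels[[1]])
  cat(sprintf("<eeg_recording: %d channels x %d samples @ %g Hz (%.2f h)>\n",
              length(x$channels), n, x$fs, n / x$fs / 3600))
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' Number of samples per channel
#' @param rec an [recording()].
#' @return integer sample count.
#' @export
n_samples <- function(rec) length(rec$channels[[1]])

# Default mapping from compact CSV column names to channel roles.
DEFAULT_CHANNEL_MAP <- c(eeg_r = "EEG_rostral", eeg_c = "EEG_caudal",
                         emg = "EMG")

#' Read a recording from CSV or EDF
#'
#' The CSV dialect has a time column `t` (seconds) followed by one
#' column per channel; the sampling rate is inferred from the spacing of
#' `t`.  Column names are mapped to channel roles through `channel_map`.
#' EDF files are read with the minimal reader in [read_edf()].
#'
#' @param path file path.
#' @param format `"csv"` or `"edf"`; default guessed from the extension.
#' @param channel_map named character vector mapping file channel labels
#'   to roles; unknown labels are an error.
#' @param zt_start ZT of the first sample (seconds).
#' @return an [recording()].
#' @export
read_recording <- function(path, format = c("auto", "csv", "edf"),
                           channel_map = DEFAULT_CHANNEL_MAP,
                           zt_start = 0) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "edf") return(read_edf(path, zt_start = zt_start))
  df <- read.csv(path)
  if (!"t" %in% names(df) || nrow(df) < 2L) {
    stop("recording CSV needs a time column 't' and >= 2 rows",
         call. = FALSE)
  }
  dt <- diff(df$t)
  if (any(abs(dt - dt[1]) > 1e-6 * dt[1])) {
    stop("time column is not uniformly spaced", call. = FALSE)
  }
  fs <- 1 / dt[1]
  cols <- setdiff(names(df), "t")
  chans <- list()
  for (cn in cols) {
    role <- if (cn %in% names(channel_map)) channel_map[[cn]] else
      if (cn %in% channel_map) cn else
        stop("unknown channel label '", cn,
             "'; extend channel_map to declare its role", call. = FALSE)
    chans[[role]] <- df[[cn]]
  }
  recording(chans, fs = fs, zt_start = zt_start)
}

#' Write a recording to CSV
#' @param rec an [recording()].
#' @param path output path.
#' @param channel_map role-to-column mapping (reverse of the read map).
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path,
                                channel_map = DEFAULT_CHANNEL_MAP) {
  inv <- stats::setNames(names(channel_map), channel_map)
  df <- data.frame(t = (seq_len(n_samples(rec)) - 1) / rec$fs)
  for (role in names(rec$channels)) {
    col <- if (role %in% names(inv)) inv[[role]] else role
    df[[col]] <- rec$channels[[role]]
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Zero-phase band-pass filter a channel
#'
#' Applies a forward-backward (zero-phase) 4th-order Butterworth
#' band-pass, the digital stand-in for the acquisition chain's analog
#' passbands (EEG 1--30 Hz, EMG 10--40 Hz).
#'
#' @param rec an [recording()].
#' @param channel channel role to filter (default: all channels).
#' @param low,high corner frequencies in Hz; `0 < low < high < fs/2`.
#' @param order Butterworth order (default 4).
#' @return the recording with the channel(s) replaced by filtered data.
#' @export
bandpass <- function(rec, channel = NULL, low, high, order = 4) {
  if (!is.numeric(low) || !is.numeric(high) ||
      low <= 0 || high <= low || high >= rec$fs / 2) {
    stop("corner frequencies must satisfy 0 < low < high < fs/2",
         call. = FALSE)
  }
  chans <- channel %||% names(rec$channels)
  bf <- signal::butter(order, c(low, high) / (rec$fs / 2), type = "pass")
  for (ch in chans) {
    if (!ch %in% names(rec$channels)) {
      stop("no such channel: ", ch, call. = FALSE)
    }
    rec$channels[[ch]] <- signal::filtfilt(bf, rec$channels[[ch]])
  }
  rec
}

#' Read an epoch-wise hypnogram from CSV
#'
#' CSV columns: `epoch_index`, `zt_seconds`, `state` with state in
#' `WAKE`/`NREM`/`REM`.  The epoch length is inferred from the spacing
#' of `zt_seconds` (or supplied for single-epoch files).
#'
#' @param path file path.
#' @param epoch_len epoch length in seconds; required only when the file
#'   has a single row.
#' @return a [hypnogram()].
#' @export
read_hypnogram <- function(path, epoch_len = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(read.csv(path, colClasses = c("integer", "numeric",
                                               "character")),
                 error = function(e) stop("cannot parse hypnogram CSV: ",
                                          conditionMessage(e), call. = FALSE))
  if (nrow(df) == 0L) {
    stop("hypnogram file is empty: ", path, call. = FALSE)
  }
  need <- c("epoch_index", "zt_seconds", "state")
  if (!all(need %in% names(df))) {
    stop("hypnogram CSV must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  bad <- which(!df$state %in% VIGILANCE_STATES)
  if (length(bad) > 0L) {
    stop(sprintf("unknown state token '%s' at row %d of %s",
                 df$state[bad[1]], bad[1], path), call. = FALSE)
  }
  if (nrow(df) >= 2L) {
    epoch_len <- df$zt_seconds[2] - df$zt_seconds[1]
  } else if (is.null(epoch_len)) {
    stop("single-epoch file: supply epoch_len explicitly", call. = FALSE)
  }
  hypnogram(df$state, epoch_len = epoch_len, zt_start = df$zt_seconds[1])
}

#' Write a hypnogram to CSV
#' @param hyp a [hypnogram()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(hyp, path) {
  df <- data.frame(epoch_index = seq_along(hyp$labels) - 1L,
                   zt_seconds = epoch_zt(hyp),
                   state = hyp$labels)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
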