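#' Spectral analysis configuration
#'
#' Defaults follow the acquisition contract of a 200 Hz rodent
#' polysomnography setup band-limited to 1--30 Hz: Welch PSD with
#' NFFT = 256 (frequency resolution 200/256 = 0.78125 Hz), Hamming
#' window, 50% overlap, and relative power normalized by the summed
#' power between 1 and 30 Hz.  Band edges are half-open intervals on bin
#' centers chosen to partition the normalization band exactly:
#' delta \[1, 4), theta \[4, 8), alpha \[8, 14), beta \[14, 30) Hz.
#'
#' @param fs sampling rate, Hz.
#' @param nfft transform length (also the Welch segment length).
#' @param overlap fractional segment overlap.
#' @param norm_band Hz interval over which relative power is normalized.
#' @param bands named list of `c(lo, hi)` Hz intervals.
#' @return list of class `spectral_config`.
#' @export
spectral_config <- function(fs = 200, nfft = 256, overlap = 0.5,
                            norm_band = c(1, 30),
                            bands = list(delta = c(1, 4), theta = c(4, 8),
                                         alpha = c(8, 14),
                                         beta = c(14, 30))) {
  stopifnot(fs > 0, nfft > 1, overlap >= 0, overlap < 1)
  if (norm_band[1] < 0 || norm_band[2] > fs / 2) {
    stop("norm_band must lie within [0, fs/2]", call. = FALSE)
  }
  structure(list(fs = fs, nfft = as.integer(nfft), overlap = overlap,
                 norm_band = norm_band, bands = bands),
            class = "spectral_config")
}

hamming_window <- function(n) {
  0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}

# Cut every epoch (row of a matrix, or vector) into overlapping
# nfft-sample segments; returns a matrix with one segment per column.
segment_epochs <- function(epochs, nfft, overlap) {
  if (is.numeric(epochs) && is.null(dim(epochs))) {
    epochs <- matrix(epochs, nrow = 1)
  }
  step <- max(1L, as.integer(round(nfft * (1 - overlap))))
  segs <- list()
  for (i in seq_len(nrow(epochs))) {
    len <- ncol(epochs)
    if (len < nfft) next
    starts <- seq(1L, len - nfft + 1L, by = step)
    for (s in starts) segs[[length(segs) + 1L]] <- epochs[i, s:(s + nfft - 1L)]
  }
  if (length(segs) == 0L) {
    stop("no segment of nfft samples fits in the supplied epochs",
         call. = FALSE)
  }
  matrix(unlist(segs), nrow = nfft)
}

#' Welch power spectral density
#'
#' Averaged modified periodograms (Hamming window, 50% overlap by
#' default) over all segments extracted from the supplied epochs,
#' matching the conventions of MATLAB's `pwelch`.  The one-sided PSD is
#' returned on the grid `k * fs / nfft`; its integral approximates the
#' signal variance (Parseval).
#'
#' @param x numeric vector, matrix of epochs (one row per epoch), or a
#'   pool from [pool_state_epochs()].
#' @param config a [spectral_config()].
#' @param state,channel,phase optional labels carried into the result.
#' @return object of class `spectral_result`: `freq` (Hz), `power`
#'   (amplitude^2/Hz), `type = "absolute"`, `n_segments`, plus labels.
#' @export
welch_psd <- function(x, config = spectral_config(), state = NULL,
                      channel = NULL, phase = NULL) {
  if (inherits(x, "absent_state")) {
    stop("cannot compute a PSD for an absent-state marker", call. = FALSE)
  }
  if (inherits(x, "state_pool")) {
    state <- state %||% x$state
    channel <- channel %||% x$channel
    x <- x$epochs
  }
  if (is.list(x) && !is.data.frame(x)) {
    x <- do.call(rbind, x)
  }
  if (length(x) == 0L) stop("empty epoch pool", call. = FALSE)
  segs <- segment_epochs(x, config$nfft, config$overlap)
  w <- hamming_window(config$nfft)
  spec <- stats::mvfft(segs * w)
  n_half <- config$nfft %/% 2 + 1L
  pxx <- rowMeans(Mod(spec[seq_len(n_half), , drop = FALSE])^2) /
    (config$fs * sum(w^2))
  pxx[2:(n_half - 1L)] <- 2 * pxx[2:(n_half - 1L)]
  structure(
    list(freq = (seq_len(n_half) - 1L) * config$fs / config$nfft,
         power = pxx, type = "absolute", n_segments = ncol(segs),
         config = config, state = state, channel = channel,
         phase = phase),
    class = "spectral_result"
  )
}

#' @export
print.spectral_result <- function(x, ...) {
  cat(sprintf("<spectral_result (%s): %d bins, %.5g-%.5g Hz, %d segments%s>\n",
              x$type, length(x$freq), min(x$freq), max(x$freq),
              x$n_segments %||% NA_integer_,
              if (!is.null(x$state)) paste0(", state ", x$state) else ""))
  invisible(x)
}

#' Normalize a PSD to relative power
#'
#' Divides each bin by the summed absolute power over the normalization
#' band (default 1--30 Hz) and restricts the output to that band, so
#' relative powers sum to exactly 1.
#'
#' @param sr an absolute [welch_psd()] result.
#' @return a `spectral_result` with `type = "relative"`.
#' @export
relative_power <- function(sr) {
  stopifnot(inherits(sr, "spectral_result"))
  if (sr$type != "absolute") {
    stop("relative_power expects an absolute PSD", call. = FALSE)
  }
  nb <- sr$config$norm_band
  keep <- sr$freq >= nb[1] & sr$freq <= nb[2]
  total <- sum(sr$power[keep])
  if (!is.finite(total) || total <= 0) {
    stop("zero total power in the normalization band", call. = FALSE)
  }
  sr$freq <- sr$freq[keep]
  sr$power <- sr$power[keep] / total
  sr$type <- "relative"
  sr
}

#' Per-epoch normalized relative power
#'
#' Alternative to the default pool-then-normalize convention of
#' [relative_power()]: each epoch's Welch PSD is normalized to relative
#' power on its own, and the per-epoch relative spectra are averaged.
#' The two conventions agree when epochs share one total power and
#' differ when epoch amplitudes vary (per-epoch normalization weights
#' every epoch equally instead of by its power).
#'
#' @param pool a [pool_state_epochs()] result (or epochs matrix).
#' @param config a [spectral_config()].
#' @return a `spectral_result` with `type = "relative"`.
#' @export
relative_power_per_epoch <- function(pool, config = spectral_config()) {
  if (is_absent(pool)) {
    stop("cannot compute a PSD for an absent-state marker", call. = FALSE)
  }
  epochs <- if (inherits(pool, "state_pool")) pool$epochs else pool
  acc <- NULL
  for (i in seq_len(nrow(epochs))) {
    rp <- relative_power(welch_psd(epochs[i, , drop = FALSE], config))
    acc <- if (is.null(acc)) rp else {
      acc$power <- acc$power + rp$power
      acc
    }
  }
  acc$power <- acc$power / nrow(epochs)
  acc$power <- acc$power / sum(acc$power)
  acc
}

#' Relative power per frequency band
#'
#' Sums relative power over bins whose center lies in the half-open band
#' `[lo, hi)`.  With the default band set this partitions the
#' normalization band, so the fractions sum to 1.
#'
#' @param sr a relative [relative_power()] result.
#' @param bands named list of `c(lo, hi)` intervals; defaults to the
#'   bands in the result's configuration.
#' @return named numeric vector of band fractions.
#' @export
band_power <- function(sr, bands = NULL) {
  stopifnot(inherits(sr, "spectral_result"))
  if (sr$type != "relative") {
    stop("band_power expects a relative PSD; call relative_power() first",
         call. = FALSE)
  }
  bands <- bands %||% sr$config$bands
  res <- sr$config$fs / sr$config$nfft
  out <- vapply(bands, function(b) {
    if (b[1] > b[2]) stop("band lo must not exceed hi", call. = FALSE)
    if (b[2] < min(sr$freq) - res || b[1] > max(sr$freq) + res) {
      stop("band [", b[1], ", ", b[2], ") lies outside the analyzed grid",
           call. = FALSE)
    }
    sum(sr$power[sr$freq >= b[1] & sr$freq < b[2]])
  }, numeric(1))
  out
}

#' Pool the EEG epochs of one vigilance state within a ZT window
#'
#' Collects all epochs scored as `state` whose start falls inside the
#' analysis window.  If the state is REM and the window contains none,
#' the temporally closest REM episode (bout) in the same light/dark
#' phase is substituted; if the whole phase contains no REM, an explicit
#' absent-state marker is returned so downstream group statistics can
#' drop the animal.
#'
#' @param rec an [recording()].
#' @param hyp an aligned [hypnogram()] (typically the 4 s rescoring);
#'   `zt_start` must match the recording and the epoch length must be an
#'   integer number of samples.
#' @param state state to pool.
#' @param window ZT seconds `c(lo, hi)`; default: the full recording.
#' @param channel channel role to extract (default `EEG_rostral`).
#' @param max_epochs optional cap on the number of pooled epochs (taken
#'   from the start of the window), to bound computation.
#' @return object of class `state_pool` (`epochs` matrix with one row
#'   per epoch, `fs`, `state`, `channel`, `n_epochs`) or an
#'   `absent_state` marker.
#' @export
pool_state_epochs <- function(rec, hyp, state, window = NULL,
                              channel = "EEG_rostral",
                              max_epochs = Inf) {
  spe <- hyp$epoch_len * rec$fs
  if (abs(spe - round(spe)) > 1e-9) {
    stop("epoch length is not an integer number of samples", call. = FALSE)
  }
  spe <- as.integer(round(spe))
  off <- (rec$zt_start - hyp$zt_start) / hyp$epoch_len
  if (abs(off - round(off)) > 1e-9) {
    stop("hypnogram and recording grids are misaligned: the recording ",
         "does not start on an epoch boundary", call. = FALSE)
  }
  if (!channel %in% names(rec$channels)) {
    stop("no such channel: ", channel, call. = FALSE)
  }
  zt <- epoch_zt(hyp)
  rec_end <- rec$zt_start + n_samples(rec) / rec$fs
  in_rec <- zt >= rec$zt_start & (zt + hyp$epoch_len) <= rec_end + 1e-9
  window <- window %||% c(rec$zt_start, rec_end)
  in_win <- zt >= window[1] & zt < window[2]
  idx <- which(hyp$labels == state & in_win & in_rec)

  if (length(idx) == 0L && state == "REM") {
    # fallback: closest REM episode in the same light/dark phase
    phase_of <- function(z) {
      if ((z %% SECONDS_PER_DAY) < SECONDS_PER_HALF_DAY) "inactive"
      else "active"
    }
    win_phase <- phase_of(window[1])
    ph <- epoch_phase(hyp)
    cand <- which(hyp$labels == "REM" & ph == win_phase & in_rec)
    if (length(cand) > 0L) {
      runs <- split(cand, cumsum(c(1L, diff(cand) != 1L)))
      dist <- vapply(runs, function(r) {
        z <- zt[r]
        min(abs(pmax(window[1] - (z + hyp$epoch_len), 0) +
                  pmax(z - window[2], 0)))
      }, numeric(1))
      idx <- runs[[which.min(dist)]]
    }
  }
  if (length(idx) == 0L) {
    return(structure(list(state = state, channel = channel,
                          window = window),
                     class = c("absent_state", "state_pool")))
  }
  if (length(idx) > max_epochs) idx <- idx[seq_len(max_epochs)]
  starts <- as.integer(round((zt[idx] - rec$zt_start) * rec$fs)) + 1L
  sig <- rec$channels[[channel]]
  epochs <- t(vapply(starts, function(s) sig[s:(s + spe - 1L)],
                     numeric(spe)))
  structure(list(epochs = epochs, fs = rec$fs, state = state,
                 channel = channel, n_epochs = length(idx),
                 epoch_len = hyp$epoch_len, window = window),
            class = "state_pool")
}

#' Is a pool an absent-state marker?
#' @param x object returned by [pool_state_epochs()].
#' @return logical.
#' @export
is_absent <- function(x) inherits(x, "absent_state")
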