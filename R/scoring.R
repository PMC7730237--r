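#' Per-epoch spectral and EMG features for sleep scoring
#'
#' Cuts a recording into scoring epochs (default 4 s) and computes, per
#' epoch: absolute EEG band powers (delta, theta, alpha, beta) for each
#' EEG channel via Welch PSD, the theta/delta ratio, and the EMG RMS
#' amplitude.  A trailing partial epoch is dropped.  The theta/delta
#' ratio is `NA` when delta power is zero (flagged, not an error).
#'
#' @param rec an [recording()] containing at least one EEG channel and
#'   (for EMG-based scoring) an `EMG` channel.
#' @param epoch_len scoring epoch in seconds.
#' @param config a [spectral_config()].
#' @param chunk number of epochs transformed per FFT block (memory
#'   bound).
#' @return data.frame of class `epoch_features`: `epoch`, `zt`, then
#'   `<channel>_<band>` power columns, `<channel>_theta_delta`, and
#'   `emg_rms`; attribute `epoch_len`.
#' @export
epoch_features <- function(rec, epoch_len = 4,
                           config = spectral_config(fs = rec$fs),
                           chunk = 2000L) {
  spe <- epoch_len * rec$fs
  if (abs(spe - round(spe)) > 1e-9) {
    stop("epoch_len * fs must be an integer", call. = FALSE)
  }
  spe <- as.integer(round(spe))
  n_ep <- n_samples(rec) %/% spe
  if (n_ep < 1L) stop("recording shorter than one epoch", call. = FALSE)
  eeg_ch <- grep("^EEG", names(rec$channels), value = TRUE)
  if (length(eeg_ch) == 0L) stop("no EEG channel present", call. = FALSE)
  out <- data.frame(epoch = seq_len(n_ep),
                    zt = rec$zt_start + (seq_len(n_ep) - 1L) * epoch_len)
  for (ch in eeg_ch) {
    bp <- matrix(NA_real_, nrow = n_ep, ncol = length(config$bands),
                 dimnames = list(NULL, names(config$bands)))
    sig <- rec$channels[[ch]]
    for (from in seq(1L, n_ep, by = chunk)) {
      to <- min(from + chunk - 1L, n_ep)
      eps <- matrix(sig[((from - 1L) * spe + 1L):(to * spe)],
                    ncol = spe, byrow = TRUE)
      bp[from:to, ] <- epoch_band_powers(eps, config)
    }
    colnames(bp) <- paste0(ch, "_", names(config$bands))
    out <- cbind(out, as.data.frame(bp))
    delta <- out[[paste0(ch, "_delta")]]
    theta <- out[[paste0(ch, "_theta")]]
    out[[paste0(ch, "_theta_delta")]] <-
      ifelse(delta > 0, theta / delta, NA_real_)
  }
  if ("EMG" %in% names(rec$channels)) {
    emg <- rec$channels[["EMG"]][seq_len(n_ep * spe)]
    out$emg_rms <- sqrt(rowMeans(matrix(emg^2, ncol = spe,
                                        byrow = TRUE)))
  }
  attr(out, "epoch_len") <- epoch_len
  class(out) <- c("epoch_features", "data.frame")
  out
}

# Absolute band powers per epoch (rows): Welch periodograms averaged
# within each epoch, then integrated over the half-open bands.
epoch_band_powers <- function(eps, config) {
  nfft <- config$nfft
  step <- max(1L, as.integer(round(nfft * (1 - config$overlap))))
  starts <- seq(1L, ncol(eps) - nfft + 1L, by = step)
  w <- hamming_window(nfft)
  n_half <- nfft %/% 2 + 1L
  freq <- (seq_len(n_half) - 1L) * config$fs / nfft
  acc <- matrix(0, nrow = nrow(eps), ncol = n_half)
  for (s in starts) {
    seg <- t(eps[, s:(s + nfft - 1L), drop = FALSE]) * w
    p <- Mod(stats::mvfft(seg)[seq_len(n_half), , drop = FALSE])^2 /
      (config$fs * sum(w^2))
    acc <- acc + t(p)
  }
  acc <- acc / length(starts)
  acc[, 2:(n_half - 1L)] <- 2 * acc[, 2:(n_half - 1L)]
  res <- config$fs / nfft
  vapply(config$bands, function(b) {
    cols <- which(freq >= b[1] & freq < b[2])
    rowSums(acc[, cols, drop = FALSE]) * res
  }, numeric(nrow(eps)))
}

#' Calibrate scoring thresholds from feature distributions
#'
#' Per-recording calibration of the threshold scorer.  The WAKE EMG
#' threshold is derived from the (bimodal) EMG RMS distribution: with
#' `emg_method = "gap"` (default) it is the geometric midpoint between
#' the 10th and 95th percentiles, which falls in the amplitude gap
#' between atonic sleep and waking muscle tone for any realistic
#' wake/sleep mixture; `"percentile"` uses a fixed percentile instead
#' (default 60th, appropriate for full-day recordings with roughly
#' balanced wake and sleep).  The NREM delta threshold is a percentile
#' of delta power (default the median) and the REM theta/delta
#' threshold a fixed dimensionless value (default 2.0).
#'
#' @param features an [epoch_features()] table.
#' @param emg_method `"gap"` or `"percentile"`.
#' @param emg_percentile,delta_percentile percentiles in `[0, 1]`.
#' @param theta_delta_threshold fixed REM ratio cut.
#' @param channel EEG channel used for the EEG-based features.
#' @return list of class `scoring_thresholds`.
#' @export
calibrate_thresholds <- function(features,
                                 emg_method = c("gap", "percentile"),
                                 emg_percentile = 0.60,
                                 delta_percentile = 0.50,
                                 theta_delta_threshold = 2.0,
                                 channel = "EEG_rostral") {
  emg_method <- match.arg(emg_method)
  if (is.null(features$emg_rms)) {
    stop("EMG features required for calibration (no EMG channel?)",
         call. = FALSE)
  }
  dcol <- paste0(channel, "_delta")
  if (is.null(features[[dcol]])) {
    stop("no features for channel ", channel, call. = FALSE)
  }
  if (max(features$emg_rms) - min(features$emg_rms) < 1e-12) {
    stop("degenerate (constant) EMG feature: cannot calibrate",
         call. = FALSE)
  }
  emg_thr <- if (emg_method == "gap") {
    q <- quantile(features$emg_rms, c(0.10, 0.95))
    if (any(q <= 0)) mean(q) else exp(mean(log(q)))
  } else {
    quantile(features$emg_rms, emg_percentile)
  }
  structure(list(
    emg_wake_threshold = unname(emg_thr),
    delta_nrem_threshold = unname(quantile(features[[dcol]],
                                           delta_percentile)),
    theta_delta_rem_threshold = theta_delta_threshold,
    channel = channel
  ), class = "scoring_thresholds")
}

#' Score epochs into vigilance states
#'
#' Transparent three-rule threshold classifier: an epoch with EMG RMS
#' above the WAKE threshold is WAKE (muscle tone dominates, regardless
#' of EEG); otherwise a theta/delta ratio above the REM threshold gives
#' REM; otherwise NREM.  A minimum-bout smoothing pass then absorbs
#' single-epoch islands into the preceding bout's state (the default
#' 1-epoch window deliberately leaves short bouts -- the object of
#' fragmentation analyses -- untouched).  Optional manual overrides
#' (`data.frame(epoch, state)`) are applied after smoothing, making the
#' scorer semi-automated.
#'
#' @param features an [epoch_features()] table.
#' @param thresholds a [calibrate_thresholds()] result.
#' @param zt_start ZT of the first epoch (defaults to the features'
#'   first `zt`).
#' @param min_bout_epochs islands up to this many epochs are absorbed
#'   (0 disables smoothing).
#' @param override optional `data.frame(epoch, state)` of forced
#'   assignments.
#' @return a [hypnogram()] on the features' epoch grid.
#' @export
score_epochs <- function(features, thresholds, zt_start = NULL,
                         min_bout_epochs = 1L, override = NULL) {
  ratio <- features[[paste0(thresholds$channel, "_theta_delta")]]
  labs <- ifelse(features$emg_rms > thresholds$emg_wake_threshold,
                 "WAKE",
                 ifelse(!is.na(ratio) &
                          ratio > thresholds$theta_delta_rem_threshold,
                        "REM", "NREM"))
  if (min_bout_epochs > 0L) {
    labs <- absorb_islands(labs, min_bout_epochs)
  }
  if (!is.null(override)) {
    bad <- setdiff(override$state, VIGILANCE_STATES)
    if (length(bad)) stop("override contains unknown state: ", bad[1],
                          call. = FALSE)
    labs[override$epoch] <- override$state
  }
  hypnogram(labs, epoch_len = attr(features, "epoch_len"),
            zt_start = zt_start %||% features$zt[1])
}

# Merge runs of length <= k into the preceding run's state (the
# following run's state for a leading island).  Never introduces a
# state that was absent before smoothing.
absorb_islands <- function(labs, k = 1L) {
  r <- rle(labs)
  while (length(r$lengths) > 1L && any(r$lengths <= k)) {
    i <- which(r$lengths <= k)[1]
    r$values[i] <- if (i > 1L) r$values[i - 1L] else r$values[i + 1L]
    r <- rle(inverse.rle(r))
  }
  inverse.rle(r)
}

#' Agreement between a scored and a truth hypnogram
#'
#' Cohen's kappa and the per-state confusion matrix (rows = truth,
#' columns = scored).
#'
#' @param scored,truth [hypnogram()]s on identical epoch grids.
#' @return list of class `score_agreement`: `kappa`, `accuracy`,
#'   `confusion`.
#' @export
score_agreement <- function(scored, truth) {
  if (abs(scored$epoch_len - truth$epoch_len) > 1e-9 ||
      length(scored$labels) != length(truth$labels)) {
    stop("epoch grids of scored and truth hypnograms do not match",
         call. = FALSE)
  }
  f <- factor(scored$labels, levels = VIGILANCE_STATES)
  g <- factor(truth$labels, levels = VIGILANCE_STATES)
  cm <- table(truth = g, scored = f)
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else 1
  structure(list(kappa = kappa, accuracy = po, confusion = cm),
            class = "score_agreement")
}

#' @export
print.score_agreement <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.3f (accuracy %.3f)\n", x$kappa,
              x$accuracy))
  print(x$confusion)
  invisible(x)
}
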