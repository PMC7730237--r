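#' Construct a hypnogram
#'
#' A hypnogram is an ordered sequence of vigilance-state labels (`WAKE`,
#' `NREM`, `REM`) on a fixed epoch grid, anchored to Zeitgeber time (ZT;
#' seconds since lights-on).  ZT 0--12 h is the inactive (lights-on)
#' phase for nocturnal rodents, ZT 12--24 h the active phase.
#'
#' @param labels character vector of vigilance states, one per epoch;
#'   each must be one of `"WAKE"`, `"NREM"`, `"REM"`.
#' @param epoch_len epoch length in seconds (typically 10 for macro
#'   scoring and 4 for the high-resolution rescoring).
#' @param zt_start ZT of the first epoch start, in seconds.
#' @return An object of class `hypnogram`.
#' @examples
#' h <- hypnogram(c("WAKE", "WAKE", "NREM", "REM"), epoch_len = 10)
#' epoch_phase(h)
#' @export
hypnogram <- function(labels, epoch_len = 10, zt_start = 0) {
  labels <- as.character(labels)
  if (length(labels) == 0L) {
    stop("hypnogram must contain at least one epoch", call. = FALSE)
  }
  bad <- setdiff(unique(labels), VIGILANCE_STATES)
  if (length(bad) > 0L) {
    stop("unknown vigilance state(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(VIGILANCE_STATES, collapse = ", "), ")",
         call. = FALSE)
  }
  if (!is.numeric(epoch_len) || length(epoch_len) != 1L || epoch_len <= 0) {
    stop("epoch_len must be a single positive number", call. = FALSE)
  }
  structure(
    list(labels = labels, epoch_len = epoch_len, zt_start = zt_start),
    class = "hypnogram"
  )
}

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf("<hypnogram: %d epochs x %gs (%.2f h), ZT start %.2f h>\n",
              length(x$labels), x$epoch_len,
              length(x$labels) * x$epoch_len / 3600, x$zt_start / 3600))
  tb <- table(factor(x$labels, levels = VIGILANCE_STATES))
  print(round(tb / length(x$labels), 3))
  invisible(x)
}

#' @export
length.hypnogram <- function(x) length(x$labels)

#' Total duration of a hypnogram in seconds
#' @param hyp a [hypnogram()].
#' @return duration in seconds.
#' @export
hypnogram_duration <- function(hyp) length(hyp$labels) * hyp$epoch_len

#' Epoch start times in Zeitgeber seconds
#' @param hyp a [hypnogram()].
#' @return numeric vector of epoch-start ZT seconds (half-open epochs
#'   `[start, start + epoch_len)`).
#' @export
epoch_zt <- function(hyp) {
  hyp$zt_start + (seq_along(hyp$labels) - 1L) * hyp$epoch_len
}

#' Light-cycle phase of each epoch
#'
#' An epoch is `inactive` (lights on) iff its start falls in
#' ZT `[0, 12 h)` modulo 24 h, and `active` otherwise.
#'
#' @param hyp a [hypnogram()].
#' @return character vector, `"inactive"` or `"active"` per epoch.
#' @export
epoch_phase <- function(hyp) {
  zt <- epoch_zt(hyp) %% SECONDS_PER_DAY
  ifelse(zt < SECONDS_PER_HALF_DAY, "inactive", "active")
}

#' Split a hypnogram by light-cycle phase
#'
#' Partitions the epochs into the inactive (lights-on, ZT 0--12 h) and
#' active (lights-off, ZT 12--24 h) phases.  The two parts carry the
#' original epoch indices so that re-interleaving them restores the
#' original hypnogram exactly, including recordings that start mid-cycle
#' and wrap around the phase boundary.
#'
#' @param hyp a [hypnogram()].
#' @return list with elements `inactive` and `active`; each is a list
#'   with `labels`, `zt` (epoch-start ZT seconds), `epoch_len`, and
#'   `index` (positions in the original hypnogram).
#' @export
split_phase <- function(hyp) {
  ph <- epoch_phase(hyp)
  zt <- epoch_zt(hyp)
  part <- function(which) {
    idx <- which(ph == which)
    list(labels = hyp$labels[idx], zt = zt[idx],
         epoch_len = hyp$epoch_len, index = idx, phase = which)
  }
  list(inactive = part("inactive"), active = part("active"))
}

#' Restrict a hypnogram to a ZT window
#'
#' @param hyp a [hypnogram()].
#' @param window numeric length-2, ZT seconds `[lo, hi)`; epochs whose
#'   start lies in the window are kept.
#' @return a [hypnogram()] covering the window (may error if empty).
#' @export
window_hypnogram <- function(hyp, window) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  zt <- epoch_zt(hyp)
  idx <- which(zt >= window[1] & zt < window[2])
  if (length(idx) == 0L) {
    stop("no epochs fall inside the requested ZT window", call. = FALSE)
  }
  hypnogram(hyp$labels[idx], hyp$epoch_len, zt_start = zt[idx[1]])
}
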