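#' Per-bin vigilance-state proportions
#'
#' Fraction of time spent in each state within consecutive time bins
#' (default 2 h), the standard summary of sleep macroarchitecture over a
#' 24 h recording.
#'
#' @param hyp a [hypnogram()].
#' @param bin bin width in seconds (default 7200 = 2 h); must be a
#'   multiple of the epoch length.  A trailing partial bin is dropped.
#' @return data.frame with `bin_start_zt` (seconds) and one fraction
#'   column per state; fractions in each row sum to 1.
#' @export
state_proportions <- function(hyp, bin = 7200) {
  epb <- bin / hyp$epoch_len
  if (abs(epb - round(epb)) > 1e-9) {
    stop("bin must be a multiple of the epoch length", call. = FALSE)
  }
  epb <- as.integer(round(epb))
  n_bins <- length(hyp$labels) %/% epb
  if (n_bins < 1L) {
    stop("hypnogram shorter than one bin", call. = FALSE)
  }
  idx <- rep(seq_len(n_bins), each = epb)
  labs <- factor(hyp$labels[seq_len(n_bins * epb)],
                 levels = VIGILANCE_STATES)
  counts <- table(idx, labs)
  out <- data.frame(bin_start_zt = hyp$zt_start +
                      (seq_len(n_bins) - 1L) * bin)
  for (s in VIGILANCE_STATES) out[[s]] <- as.numeric(counts[, s]) / epb
  out
}

#' Extract bouts (maximal same-state runs) from a hypnogram
#'
#' A bout is the time an animal resides in one vigilance state, i.e. a
#' maximal run of identical epoch labels.  A bout spanning the light/dark
#' boundary is assigned to the phase containing its first epoch.
#'
#' @param hyp a [hypnogram()].
#' @param drop_boundary drop the first and last bout (those truncated by
#'   the recording edges)?  Default `FALSE`.
#' @return data.frame with columns `state`, `start_zt` (seconds),
#'   `duration` (seconds), `phase`.
#' @export
extract_bouts <- function(hyp, drop_boundary = FALSE) {
  r <- rle(hyp$labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  zt <- epoch_zt(hyp)
  ph <- epoch_phase(hyp)
  out <- data.frame(state = r$values,
                    start_zt = zt[starts],
                    duration = r$lengths * hyp$epoch_len,
                    phase = ph[starts],
                    stringsAsFactors = FALSE)
  if (drop_boundary && nrow(out) > 2L) {
    out <- out[-c(1L, nrow(out)), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Empirical cumulative distribution of bout lengths
#'
#' Builds the cumulative probability function over bout durations for
#' one state (optionally one phase), the representation used to compare
#' bout-length distributions between groups, together with a quantile
#' readout (e.g. the duration below which 80% of bouts fall).
#'
#' @param bouts a bout table from [extract_bouts()], or a numeric vector
#'   of durations.
#' @param state,phase optional filters applied when `bouts` is a table.
#' @return object of class `bout_ecdf`: list with `durations` (sorted),
#'   `n`, `cumprob(q)` (right-continuous ECDF), and `quantile(p)`
#'   (type-7 linear interpolation).  If no bouts match, an object with
#'   `n = 0` and `empty = TRUE` is returned as an explicit
#'   empty-distribution marker.
#' @examples
#' e <- bout_cumprob(c(10, 20, 30, 40, 50))
#' e$cumprob(30)   # 0.6
#' e$quantile(0.8) # 42
#' @export
bout_cumprob <- function(bouts, state = NULL, phase = NULL) {
  d <- if (is.data.frame(bouts)) {
    keep <- rep(TRUE, nrow(bouts))
    if (!is.null(state)) keep <- keep & bouts$state == state
    if (!is.null(phase)) keep <- keep & bouts$phase == phase
    bouts$duration[keep]
  } else {
    as.numeric(bouts)
  }
  if (length(d) == 0L) {
    return(structure(list(n = 0L, empty = TRUE, state = state,
                          phase = phase),
                     class = "bout_ecdf"))
  }
  d <- sort(d)
  structure(
    list(durations = d, n = length(d), empty = FALSE,
         state = state, phase = phase,
         cumprob = function(q) vapply(q, function(qi) mean(d <= qi), 0),
         quantile = function(p) unname(quantile(d, p, type = 7))),
    class = "bout_ecdf"
  )
}

#' @export
print.bout_ecdf <- function(x, ...) {
  if (x$empty) {
    cat("<bout_ecdf: empty distribution (no bouts)>\n")
  } else {
    cat(sprintf("<bout_ecdf: n = %d, median %.0f s, 80th pct %.0f s>\n",
                x$n, x$quantile(0.5), x$quantile(0.8)))
  }
  invisible(x)
}

#' Count transitions between WAKE and SLEEP
#'
#' Counts label changes across the binary partition WAKE versus SLEEP
#' (NREM and REM combined); NREM/REM alternations within sleep are not
#' transitions under this definition.  By parity, the two directed
#' counts can differ by at most one.
#'
#' @param hyp a [hypnogram()], or a phase part from [split_phase()]
#'   (counted within contiguous segments only).
#' @param merge_sleep combine NREM and REM into SLEEP (default `TRUE`);
#'   if `FALSE`, every label change is counted (directed counts refer to
#'   the WAKE boundary regardless).
#' @return list of class `transition_count`: `n_wake_to_sleep`,
#'   `n_sleep_to_wake`, `n_total`, `epoch_len`.
#' @export
count_transitions <- function(hyp, merge_sleep = TRUE) {
  if (inherits(hyp, "hypnogram")) {
    labs <- hyp$labels
    epoch_len <- hyp$epoch_len
    seg <- rep(1L, length(labs))
  } else {
    labs <- hyp$labels
    epoch_len <- hyp$epoch_len
    seg <- cumsum(c(1L, diff(hyp$index) != 1L))
  }
  awake <- labs == "WAKE"
  same_seg <- seg[-1] == seg[-length(seg)]
  w2s <- sum(awake[-length(awake)] & !awake[-1] & same_seg)
  s2w <- sum(!awake[-length(awake)] & awake[-1] & same_seg)
  n_total <- if (merge_sleep) w2s + s2w else
    sum((labs[-1] != labs[-length(labs)]) & same_seg)
  structure(list(n_wake_to_sleep = w2s, n_sleep_to_wake = s2w,
                 n_total = n_total, epoch_len = epoch_len),
            class = "transition_count")
}

#' @export
print.transition_count <- function(x, ...) {
  cat(sprintf(
    "<transitions (epoch %gs): WAKE->SLEEP %d, SLEEP->WAKE %d, total %d>\n",
    x$epoch_len, x$n_wake_to_sleep, x$n_sleep_to_wake, x$n_total))
  invisible(x)
}
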