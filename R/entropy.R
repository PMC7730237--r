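#' Sign-pattern motifs of a time series
#'
#' Reduces an amplitude series to the sequence of sign patterns of
#' consecutive differences inside lagged motifs.  Motif `i` (1-based)
#' collects the values `x[i], x[i + tau], ..., x[i + (m-1) tau]`; its
#' pattern is the sign (`+`/`-`) of each of the `m - 1` within-motif
#' differences.  The series `(5, 4, 6, 2, 3, 1)` with `m = 3, tau = 1`
#' yields the four patterns `-+`, `+-`, `-+`, `+-`.
#'
#' @param x numeric series.
#' @param m embedding dimension (motif length), `>= 2`.
#' @param tau lag in samples, `>= 1` (1 probes fast dynamics, larger
#'   lags slower dynamics).
#' @param tie_policy how an exact zero difference is encoded:
#'   `"merge_down"` (default) maps it to `-`; `"third_symbol"` keeps a
#'   separate `0` symbol.
#' @return character vector of patterns, one per motif; length
#'   `length(x) - (m - 1) * tau`.
#' @export
sign_motifs <- function(x, m = 5, tau = 1,
                        tie_policy = c("merge_down", "third_symbol")) {
  tie_policy <- match.arg(tie_policy)
  if (m < 2 || tau < 1) stop("need m >= 2 and tau >= 1", call. = FALSE)
  n <- length(x)
  n_mot <- n - (m - 1) * tau
  if (n_mot < 1L) {
    stop("series too short: need length >= (m - 1) * tau + 1",
         call. = FALSE)
  }
  codes <- sign_pattern_codes(x, m, tau, tie_policy)
  sign_pattern_labels(m, tie_policy)[codes + 1L]
}

# Integer encoding of the sign patterns (base 2 for merge_down, base 3
# for third_symbol); the fast path shared by sign_motifs and the
# entropy computations.
sign_pattern_codes <- function(x, m, tau, tie_policy = "merge_down") {
  n_mot <- length(x) - (m - 1L) * tau
  codes <- integer(n_mot)
  radix <- if (tie_policy == "merge_down") 2L else 3L
  for (k in seq_len(m - 1L)) {
    d <- x[(k * tau + 1L):(k * tau + n_mot)] -
      x[((k - 1L) * tau + 1L):((k - 1L) * tau + n_mot)]
    sym <- if (tie_policy == "merge_down") as.integer(d > 0)
    else as.integer(d > 0) + 2L * as.integer(d == 0)
    codes <- codes * radix + sym
  }
  codes
}

# Pattern strings indexed by code + 1, e.g. "-+" for m = 3.
sign_pattern_labels <- function(m, tie_policy = "merge_down") {
  syms <- if (tie_policy == "merge_down") c("-", "+") else c("-", "+", "0")
  out <- ""
  for (k in seq_len(m - 1L)) {
    out <- as.vector(t(outer(out, syms, paste0)))
  }
  out
}

shannon_bits <- function(counts) {
  counts <- counts[counts > 0]
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

#' Entropy of difference (EoD)
#'
#' Shannon entropy (base 2) of the empirical distribution of
#' sign-pattern motifs of a series: high when the `2^(m-1)` patterns
#' occur uniformly (information-rich, noise-like signal), and 0 when a
#' single pattern occurs, as for any strictly monotone series.  With
#' `normalize = TRUE` the entropy is divided by its `m - 1` bit maximum
#' so values lie in `[0, 1]` and are comparable across lags.
#'
#' @inheritParams sign_motifs
#' @param normalize divide by `m - 1` bits (default `TRUE`).
#' @return a single EoD value.
#' @examples
#' entropy_of_difference(c(5, 4, 6, 2, 3, 1), m = 3, tau = 1,
#'                       normalize = FALSE) # 1 bit
#' @export
entropy_of_difference <- function(x, m = 5, tau = 1, normalize = TRUE,
                                  tie_policy = "merge_down") {
  if (m < 2 || tau < 1) stop("need m >= 2 and tau >= 1", call. = FALSE)
  if (length(x) < (m - 1) * tau + 1) {
    stop("series too short: need length >= (m - 1) * tau + 1",
         call. = FALSE)
  }
  radix <- if (tie_policy == "merge_down") 2L else 3L
  codes <- sign_pattern_codes(x, m, tau, tie_policy)
  h <- shannon_bits(tabulate(codes + 1L, nbins = radix^(m - 1L)))
  if (normalize) h / (m - 1) else h
}

#' Permutation entropy (PeEn)
#'
#' Rank-pattern analogue of the entropy of difference: each motif is
#' encoded by the permutation that sorts it (ties broken by temporal
#' order) and the Shannon entropy (base 2) of the pattern distribution
#' is returned; the maximum is `log2(m!)` bits.
#'
#' @inheritParams sign_motifs
#' @param normalize divide by `log2(m!)` (default `FALSE`).
#' @return a single PeEn value.
#' @export
permutation_entropy <- function(x, m = 3, tau = 1, normalize = FALSE) {
  if (m < 2 || tau < 1) stop("need m >= 2 and tau >= 1", call. = FALSE)
  n <- length(x)
  n_mot <- n - (m - 1) * tau
  if (n_mot < 1L) {
    stop("series too short: need length >= (m - 1) * tau + 1",
         call. = FALSE)
  }
  mot <- vapply(seq_len(n_mot), function(i) {
    x[i + (0:(m - 1)) * tau]
  }, numeric(m))
  pats <- apply(mot, 2L, function(v) {
    paste0(rank(v, ties.method = "first"), collapse = ",")
  })
  h <- shannon_bits(table(pats))
  if (normalize) h / log2(factorial(m)) else h
}

#' Pooled EoD of one vigilance state
#'
#' Pools the sign-pattern counts over all epochs of a state within an
#' analysis window (motifs never cross epoch boundaries, since pooled
#' epochs are not temporally contiguous) and returns the entropy of the
#' pooled distribution.  Epochs shorter than one motif span are
#' skipped.  For an absent-state marker (e.g. an animal without REM in
#' the phase) `NA` is returned with attribute `absent = TRUE`.
#'
#' @param rec an [recording()].
#' @param hyp aligned 4 s [hypnogram()].
#' @param state state to analyse.
#' @param window ZT seconds `c(lo, hi)`.
#' @inheritParams entropy_of_difference
#' @param channel channel role.
#' @param max_epochs optional cap on pooled epochs.
#' @return EoD value (or `NA` for an absent state).
#' @export
eod_by_state <- function(rec, hyp, state, window = NULL, m = 5, tau = 1,
                         normalize = TRUE, tie_policy = "merge_down",
                         channel = "EEG_rostral", max_epochs = Inf) {
  pool <- pool_state_epochs(rec, hyp, state, window = window,
                            channel = channel, max_epochs = max_epochs)
  eod_of_pool(pool, m = m, tau = tau, normalize = normalize,
              tie_policy = tie_policy)
}

#' EoD of an epoch pool
#' @param pool a [pool_state_epochs()] result.
#' @inheritParams entropy_of_difference
#' @return EoD value, or `NA` with attribute `absent` for an
#'   absent-state marker.
#' @export
eod_of_pool <- function(pool, m = 5, tau = 1, normalize = TRUE,
                        tie_policy = "merge_down") {
  if (is_absent(pool)) {
    return(structure(NA_real_, absent = TRUE))
  }
  span <- (m - 1) * tau + 1
  radix <- if (tie_policy == "merge_down") 2L else 3L
  counts <- integer(radix^(m - 1L))
  any_epoch <- FALSE
  for (i in seq_len(nrow(pool$epochs))) {
    ep <- pool$epochs[i, ]
    if (length(ep) < span) next
    any_epoch <- TRUE
    codes <- sign_pattern_codes(ep, m, tau, tie_policy)
    counts <- counts + tabulate(codes + 1L, nbins = length(counts))
  }
  if (!any_epoch) {
    stop("no epoch long enough for a single motif", call. = FALSE)
  }
  h <- shannon_bits(counts)
  if (normalize) h / (m - 1) else h
}
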