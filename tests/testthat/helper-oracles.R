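# Independent brute-force oracles used across the suite.  These are
# deliberately naive re-implementations (linear scans, nested loops,
# exhaustive enumeration) kept separate from the package's own code
# paths.

# Run-length encoding by linear scan.
oracle_bouts <- function(labels) {
  states <- character(0); lengths <- integer(0)
  cur <- labels[1]; len <- 1L
  for (i in seq_along(labels)[-1]) {
    if (labels[i] == cur) {
      len <- len + 1L
    } else {
      states <- c(states, cur); lengths <- c(lengths, len)
      cur <- labels[i]; len <- 1L
    }
  }
  data.frame(state = c(states, cur), length = c(lengths, len))
}

# WAKE/SLEEP transition count by scanning the binarized sequence.
oracle_transitions <- function(labels) {
  awake <- labels == "WAKE"
  n <- 0L
  for (i in seq_along(awake)[-1]) {
    if (awake[i] != awake[i - 1L]) n <- n + 1L
  }
  n
}

# Entropy of difference by explicit motif extraction and counting.
oracle_eod <- function(x, m, tau, normalize = TRUE) {
  n_mot <- length(x) - (m - 1) * tau
  pats <- character(n_mot)
  for (i in seq_len(n_mot)) {
    motif <- x[i + (0:(m - 1)) * tau]
    signs <- character(m - 1)
    for (k in seq_len(m - 1)) {
      signs[k] <- if (motif[k + 1] - motif[k] > 0) "+" else "-"
    }
    pats[i] <- paste(signs, collapse = "")
  }
  tab <- table(pats)
  p <- tab / sum(tab)
  h <- -sum(p * log2(p))
  if (normalize) h / (m - 1) else h
}

# AUC by double loop over all pairs.
oracle_auc <- function(a, b) {
  wins <- 0
  for (ai in a) for (bi in b) {
    if (bi > ai) wins <- wins + 1
    else if (bi == ai) wins <- wins + 0.5
  }
  wins / (length(a) * length(b))
}

# Long-run state occupancy of the semi-Markov chain by direct
# simulation (independent of the package's generator internals).
oracle_stationary <- function(mean_dur, sdlog, trans, n_bouts = 2e5,
                              seed = 424242) {
  set.seed(seed)
  states <- c("WAKE", "NREM", "REM")
  time_in <- c(WAKE = 0, NREM = 0, REM = 0)
  s <- "WAKE"
  for (i in seq_len(n_bouts)) {
    d <- rlnorm(1, log(mean_dur[[s]]) - sdlog^2 / 2, sdlog)
    time_in[s] <- time_in[s] + d
    s <- sample(states, 1, prob = trans[s, ])
  }
  time_in / sum(time_in)
}

# A small cohort with EEG confined to one window; shared by scoring /
# pipeline tests.
make_test_cohort <- function(seed = 7, n_ac = 3, n_ad = 3,
                             duration = 24 * 3600,
                             window = c(7, 8) * 3600,
                             channels = c("EEG_rostral", "EMG")) {
  cfg <- simulation_config(n_ac = n_ac, n_ad = n_ad,
                           duration = duration, seed = seed)
  simulate_cohort(cfg, eeg_windows = list(window), channels = channels)
}

# Wrap an epochs matrix as a state_pool object.
make_pool <- function(epochs, fs = 200, state = "WAKE") {
  structure(list(epochs = epochs, fs = fs, state = state,
                 channel = "EEG_rostral", n_epochs = nrow(epochs)),
            class = "state_pool")
}
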