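test_that("epoch features recover dominant rhythms and handle edge
          cases", {
  fs <- 200
  # pure 2 Hz tone: delta carries > 90% of 1-30 Hz power
  tone <- sin(2 * pi * 2 * (0:(fs * 4 - 1)) / fs)
  rec <- recording(list(EEG_rostral = tone), fs = fs)
  fx <- epoch_features(rec, epoch_len = 4)
  expect_equal(nrow(fx), 1)  # 800 samples = exactly one 4 s epoch
  bands <- unlist(fx[1, paste0("EEG_rostral_",
                               c("delta", "theta", "alpha", "beta"))])
  expect_gt(bands[1] / sum(bands), 0.9)
  # zero signal: zero powers, ratio flagged NA
  rec0 <- recording(list(EEG_rostral = numeric(800), EMG = numeric(800)),
                    fs = fs)
  fx0 <- epoch_features(rec0, epoch_len = 4)
  expect_equal(fx0$EEG_rostral_delta, 0)
  expect_true(is.na(fx0$EEG_rostral_theta_delta))
  expect_equal(fx0$emg_rms, 0)
  # shorter than one epoch
  expect_error(epoch_features(recording(list(EEG_rostral = rnorm(100)),
                                        fs = fs), epoch_len = 4),
               "shorter than one epoch")
})

test_that("calibration uses the stated percentiles and rejects
          degenerate features", {
  set.seed(40)
  fx <- data.frame(emg_rms = runif(200), EEG_rostral_delta = runif(200),
                   EEG_rostral_theta_delta = runif(200))
  attr(fx, "epoch_len") <- 4
  th <- calibrate_thresholds(fx, emg_method = "percentile")
  expect_equal(th$emg_wake_threshold, quantile(fx$emg_rms, 0.6),
               ignore_attr = TRUE)
  # percentile 0/100 give min/max
  th0 <- calibrate_thresholds(fx, emg_method = "percentile",
                              emg_percentile = 0,
                              delta_percentile = 1)
  expect_equal(th0$emg_wake_threshold, min(fx$emg_rms))
  expect_equal(th0$delta_nrem_threshold, max(fx$EEG_rostral_delta))
  # the gap rule lands between the bulk of sleep and wake amplitudes
  emg_bimodal <- c(rnorm(120, 0.3, 0.03), rnorm(80, 1.0, 0.1))
  fxg <- data.frame(emg_rms = emg_bimodal,
                    EEG_rostral_delta = runif(200),
                    EEG_rostral_theta_delta = runif(200))
  attr(fxg, "epoch_len") <- 4
  thg <- calibrate_thresholds(fxg)
  expect_gt(thg$emg_wake_threshold, 0.45)
  expect_lt(thg$emg_wake_threshold, 0.85)
  fx$emg_rms <- 1
  expect_error(calibrate_thresholds(fx), "degenerate")
})

test_that("the decision rules apply in order: EMG, then theta/delta", {
  fx <- data.frame(epoch = 1:3, zt = c(0, 4, 8),
                   EEG_rostral_delta = c(1, 1, 1),
                   EEG_rostral_theta_delta = c(5, 5, 0.5),
                   emg_rms = c(10, 0.1, 0.1))
  attr(fx, "epoch_len") <- 4
  th <- structure(list(emg_wake_threshold = 1,
                       delta_nrem_threshold = 0.5,
                       theta_delta_rem_threshold = 2,
                       channel = "EEG_rostral"),
                  class = "scoring_thresholds")
  h <- score_epochs(fx, th, min_bout_epochs = 0)
  # high EMG wins regardless of a REM-like ratio; then ratio splits
  expect_equal(h$labels, c("WAKE", "REM", "NREM"))
})

test_that("smoothing absorbs islands and never creates new states", {
  labs <- c("WAKE", "WAKE", "REM", "WAKE", "NREM", "NREM")
  sm <- sleeparch:::absorb_islands(labs, 1L)
  expect_equal(sm, c("WAKE", "WAKE", "WAKE", "WAKE", "NREM", "NREM"))
  set.seed(41)
  for (rep in 1:50) {
    labs <- sample(c("WAKE", "NREM", "REM"), 60, replace = TRUE)
    sm <- sleeparch:::absorb_islands(labs, 1L)
    expect_true(all(sm %in% unique(labs)))
    expect_true(all(rle(sm)$lengths >= 2) || length(rle(sm)$lengths) == 1)
  }
})

test_that("manual overrides are applied after smoothing", {
  fx <- data.frame(epoch = 1:4, zt = seq(0, 12, 4),
                   EEG_rostral_delta = 1, EEG_rostral_theta_delta = 0.1,
                   emg_rms = 10)
  attr(fx, "epoch_len") <- 4
  th <- structure(list(emg_wake_threshold = 1, delta_nrem_threshold = 1,
                       theta_delta_rem_threshold = 2,
                       channel = "EEG_rostral"),
                  class = "scoring_thresholds")
  h <- score_epochs(fx, th,
                    override = data.frame(epoch = 2, state = "REM"))
  expect_equal(h$labels, c("WAKE", "REM", "WAKE", "WAKE"))
  expect_error(score_epochs(fx, th,
                            override = data.frame(epoch = 1,
                                                  state = "N2")),
               "unknown state")
})

test_that("agreement is 1 on identity, negative on disjoint labels,
          near 0 after shuffling", {
  set.seed(42)
  labs <- sample(c("WAKE", "NREM", "REM"), 600, replace = TRUE,
                 prob = c(0.5, 0.4, 0.1))
  h <- hypnogram(labs, epoch_len = 4)
  expect_equal(score_agreement(h, h)$kappa, 1)
  flip <- c(WAKE = "NREM", NREM = "REM", REM = "WAKE")
  expect_lt(score_agreement(hypnogram(unname(flip[labs]), 4), h)$kappa, 0)
  shuffled <- hypnogram(sample(labs), epoch_len = 4)
  expect_lt(abs(score_agreement(shuffled, h)$kappa), 0.1)
  expect_error(score_agreement(hypnogram(labs[1:10], 4), h),
               "grids")
})

test_that("the threshold scorer recovers generator truth with high
          kappa", {
  # score a segment spanning both phases, so the EMG percentile
  # calibration sees a representative wake/sleep mixture
  coh <- make_test_cohort(seed = 99, n_ac = 1, n_ad = 1,
                          duration = 15 * 3600,
                          window = c(9, 15) * 3600)
  kap <- vapply(coh$animals, function(an) {
    fx <- epoch_features(an$recordings[[1]], epoch_len = 4)
    sc <- score_epochs(fx, calibrate_thresholds(fx))
    truth <- window_hypnogram(an$hyp_micro, c(9, 15) * 3600)
    score_agreement(sc, truth)$kappa
  }, numeric(1))
  expect_true(all(kap >= 0.8))
})
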