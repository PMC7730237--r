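test_that("the default grid has the 200/256 Hz bin width", {
  sr <- welch_psd(rnorm(800), spectral_config())
  expect_equal(diff(sr$freq)[1], 200 / 256)
  expect_equal(diff(sr$freq)[1], 0.78125)
})

test_that("Welch PSD is Parseval-consistent on white noise", {
  set.seed(30)
  x <- rnorm(200 * 400)
  sr <- welch_psd(matrix(x, nrow = 100, byrow = TRUE))
  expect_equal(sum(sr$power) * 200 / 256, var(x), tolerance = 0.05)
})

test_that("Welch matches a direct periodogram-average oracle", {
  set.seed(31)
  x <- rnorm(256 * 4)
  cfg <- spectral_config(overlap = 0)  # disjoint segments
  sr <- welch_psd(matrix(x, nrow = 1), cfg)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:255) / 255)
  acc <- numeric(129)
  for (s in seq(1, 769, by = 256)) {
    seg <- x[s:(s + 255)] * w
    p <- Mod(fft(seg))[1:129]^2 / (200 * sum(w^2))
    p[2:128] <- 2 * p[2:128]
    acc <- acc + p
  }
  expect_equal(sr$power, acc / 4, tolerance = 1e-10)
})

test_that("a 10 Hz tone peaks at the nearest bin", {
  tone <- sin(2 * pi * 10 * (0:79999) / 200)
  sr <- welch_psd(matrix(tone, nrow = 100, byrow = TRUE))
  expect_equal(sr$freq[which.max(sr$power)], 10.15625)
})

test_that("relative power sums to 1 and is amplitude-scale invariant", {
  set.seed(32)
  x <- matrix(rnorm(800 * 20), nrow = 20)
  rp <- relative_power(welch_psd(x))
  expect_equal(sum(rp$power), 1, tolerance = 1e-9)
  expect_true(all(rp$freq >= 1 & rp$freq <= 30))
  rp2 <- relative_power(welch_psd(2 * x))
  expect_equal(rp2$power, rp$power, tolerance = 1e-12)
})

test_that("two tones with 3:1 power ratio give 0.75/0.25 relative
          power", {
  t <- (0:79999) / 200
  x <- sqrt(3) * sin(2 * pi * 10.15625 * t) + sin(2 * pi * 20.3125 * t)
  rp <- relative_power(welch_psd(matrix(x, nrow = 100, byrow = TRUE)))
  near <- function(f0) sum(rp$power[abs(rp$freq - f0) < 1])
  expect_equal(near(10.15625), 0.75, tolerance = 0.01)
  expect_equal(near(20.3125), 0.25, tolerance = 0.01)
})

test_that("zero signal is a zero-total-power error", {
  sr <- welch_psd(matrix(0, nrow = 2, ncol = 800))
  expect_error(relative_power(sr), "zero total power")
})

test_that("band powers partition the normalization band", {
  set.seed(33)
  rp <- relative_power(welch_psd(matrix(rnorm(800 * 10), nrow = 10)))
  bp <- band_power(rp)
  expect_equal(sum(bp), 1, tolerance = 1e-9)
  expect_equal(band_power(rp, list(empty = c(5, 5)))[["empty"]], 0)
  expect_error(band_power(rp, list(bad = c(60, 80))), "outside")
})

test_that("pooling selects state epochs within the window", {
  set.seed(34)
  labs <- rep(c("WAKE", "NREM"), each = 50)
  h <- hypnogram(labs, epoch_len = 4)
  rec <- recording(list(EEG_rostral = rnorm(400 * 200 * 2 / 2)), fs = 200)
  pool <- pool_state_epochs(rec, h, "NREM", window = c(200, 280))
  expect_equal(pool$n_epochs, 20)
  # all-NREM window: pool is the whole window
  pool2 <- pool_state_epochs(rec, h, "NREM", window = c(200, 400))
  expect_equal(pool2$n_epochs, 50)
})

test_that("REM fallback substitutes the closest episode in the same
          phase", {
  # REM exists only at ZT 10 h; window is ZT 7-9 h
  labs <- rep("NREM", 10800)             # 12 h of 4 s epochs
  labs[9000:9014] <- "REM"               # ZT 10 h
  h <- hypnogram(labs, epoch_len = 4)
  rec <- recording(list(EEG_rostral = rnorm(10800 * 800)), fs = 200)
  pool <- pool_state_epochs(rec, h, "REM", window = c(7, 9) * 3600)
  expect_false(is_absent(pool))
  expect_equal(pool$n_epochs, 15)
  # no REM anywhere in the phase: explicit absent marker
  h2 <- hypnogram(rep("NREM", 10800), epoch_len = 4)
  pool2 <- pool_state_epochs(rec, h2, "REM", window = c(7, 9) * 3600)
  expect_true(is_absent(pool2))
  # an absent marker is not a valid PSD input
  expect_error(welch_psd(pool2), "absent")
})

test_that("misaligned grids are rejected", {
  h <- hypnogram(rep("WAKE", 10), epoch_len = 4, zt_start = 1)
  rec <- recording(list(EEG_rostral = rnorm(8000)), fs = 200)
  expect_error(pool_state_epochs(rec, h, "WAKE"), "misaligned")
})

test_that("per-epoch normalization agrees with pooling for
          equal-power epochs and down-weights loud epochs otherwise", {
  set.seed(35)
  eps <- matrix(rnorm(6 * 800), nrow = 6)
  pooled <- relative_power(welch_psd(eps))
  per_ep <- relative_power_per_epoch(eps)
  expect_equal(per_ep$power, pooled$power, tolerance = 0.05)
  expect_equal(sum(per_ep$power), 1, tolerance = 1e-9)
  # one very loud delta-heavy epoch dominates the pooled estimate but
  # counts once under per-epoch normalization
  loud <- 50 * sin(2 * pi * 2 * (0:799) / 200) + rnorm(800, sd = 0.1)
  eps2 <- rbind(eps, loud)
  pooled2 <- relative_power(welch_psd(eps2))
  per_ep2 <- relative_power_per_epoch(eps2)
  delta <- function(sr) sum(sr$power[sr$freq >= 1 & sr$freq < 4])
  expect_gt(delta(pooled2), delta(per_ep2))
})
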