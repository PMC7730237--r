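test_that("profile and configuration invariants are enforced", {
  expect_error(group_effect_profile(bout_scale = c(WAKE = 0, NREM = 1,
                                                   REM = 1)),
               "> 0")
  expect_error(group_effect_profile(
    relpower = list(WAKE = c(delta = 0.9, theta = 0.3, alpha = 0,
                             beta = 0),
                    NREM = c(delta = 0.5, theta = 0.1, alpha = 0.1,
                             beta = 0.1),
                    REM = c(delta = 0.5, theta = 0.1, alpha = 0.1,
                            beta = 0.1))),
    "sum to <= 1")
  expect_error(group_effect_profile(rem_deficit_prob = 1.5), "\\[0, 1\\]")
  expect_error(simulation_config(duration = 86405), "multiple")
  expect_error(simulation_config(fs = 60), "twice")
  bad <- matrix(c(0.5, 0.5, 0, 1, 0, 0, 1, 0, 0), nrow = 3,
                byrow = TRUE,
                dimnames = list(c("WAKE", "NREM", "REM"),
                                c("WAKE", "NREM", "REM")))
  expect_error(semi_markov_params(trans = bad), "zero diagonal")
})

test_that("hypnogram simulation is deterministic under a fixed seed", {
  h1 <- simulate_hypnogram(4 * 3600, seed = 3)
  h2 <- simulate_hypnogram(4 * 3600, seed = 3)
  expect_identical(h1$labels, h2$labels)
  h3 <- simulate_hypnogram(4 * 3600, seed = 4)
  expect_false(identical(h1$labels, h3$labels))
})

test_that("a WAKE-absorbing chain yields an all-WAKE hypnogram with no
          transitions", {
  trans <- matrix(c(0, 1, 0, 1, 0, 0, 1, 0, 0), nrow = 3, byrow = TRUE,
                  dimnames = list(c("WAKE", "NREM", "REM"),
                                  c("WAKE", "NREM", "REM")))
  base <- semi_markov_params(
    mean_dur_inactive = c(WAKE = 1e7, NREM = 100, REM = 100),
    mean_dur_active = c(WAKE = 1e7, NREM = 100, REM = 100),
    sdlog = 0.1, trans = trans)
  h <- simulate_hypnogram(24 * 3600, base = base, seed = 5)
  expect_true(all(h$labels == "WAKE"))
  expect_equal(count_transitions(h)$n_total, 0)
})

test_that("cohort state proportions match the renewal-theory stationary
          law from a brute-force long run", {
  base <- semi_markov_params()
  # single-phase chain (inactive parameters throughout)
  one_phase <- semi_markov_params(
    mean_dur_active = base$mean_dur$inactive)
  prof <- group_effect_profile()
  props <- t(vapply(1:100, function(i) {
    h <- simulate_hypnogram(24 * 3600, prof, one_phase, seed = 6000 + i)
    tab <- table(factor(h$labels, levels = c("WAKE", "NREM", "REM")))
    as.numeric(tab) / length(h$labels)
  }, numeric(3)))
  target <- oracle_stationary(base$mean_dur$inactive, base$sdlog,
                              base$trans, n_bouts = 2e5)
  se <- apply(props, 2, sd) / sqrt(nrow(props))
  # discretization to 10 s epochs biases occupancy slightly; allow the
  # oracle comparison 2 SE plus a 0.01 discretization margin
  expect_true(all(abs(colMeans(props) - target) < 2 * se + 0.01))
})

test_that("halving the NREM bout scale stochastically shortens NREM
          bouts", {
  short_prof <- group_effect_profile(bout_scale = c(WAKE = 1,
                                                    NREM = 0.5,
                                                    REM = 1))
  ref <- group_effect_profile()
  pool <- function(prof, seeds) {
    unlist(lapply(seeds, function(s) {
      b <- extract_bouts(simulate_hypnogram(24 * 3600, prof, seed = s))
      b$duration[b$state == "NREM"]
    }))
  }
  a <- pool(ref, 0:19)
  b <- pool(short_prof, 0:19)
  expect_lt(median(b), median(a))
  expect_lt(anderson_darling_2samp(a, b)$p, 0.05)
})

test_that("REM is entered only from NREM under the default chain", {
  h <- simulate_hypnogram(48 * 3600, seed = 77)
  b <- extract_bouts(h)
  pre_rem <- b$state[which(b$state == "REM") - 1L]
  expect_true(all(pre_rem == "NREM"))
})

test_that("synthesized EEG hits the relative-power targets through the
          spectral module", {
  prof <- group_effect_profile()
  hyp <- hypnogram(rep("NREM", 150), epoch_len = 4)
  rec <- simulate_eeg(hyp, prof, fs = 200, seed = 60)
  rp <- relative_power(welch_psd(pool_state_epochs(rec, hyp, "NREM")))
  bp <- band_power(rp)
  targets <- prof$relpower$NREM
  broad <- 1 - sum(targets)
  bw <- c(delta = 3, theta = 4, alpha = 6, beta = 16)
  expect_true(all(abs(bp - (targets + broad * bw / 29)) < 0.05))
  # delta target 0.62: measured well within +-0.05
  expect_gt(bp[["delta"]], 0.57)
  expect_lt(bp[["delta"]], 0.70)
})

test_that("synthesized EMG amplitude ranks WAKE > NREM > REM", {
  prof <- group_effect_profile()
  hyp <- hypnogram(rep(c("WAKE", "NREM", "REM"), each = 30),
                   epoch_len = 4)
  rec <- simulate_eeg(hyp, prof, fs = 200, seed = 61)
  fx <- epoch_features(rec, epoch_len = 4)
  med <- tapply(fx$emg_rms, hyp$labels, median)
  expect_gt(med[["WAKE"]], med[["NREM"]])
  expect_gt(med[["NREM"]], med[["REM"]])
})

test_that("EEG synthesis is deterministic and validates the fs
          contract", {
  prof <- group_effect_profile()
  hyp <- hypnogram(rep("WAKE", 10), epoch_len = 4)
  r1 <- simulate_eeg(hyp, prof, seed = 62)
  r2 <- simulate_eeg(hyp, prof, seed = 62)
  expect_identical(r1$channels, r2$channels)
  expect_error(simulate_eeg(hypnogram(rep("WAKE", 10),
                                      epoch_len = 1 / 3),
                            prof, fs = 200), "mismatch")
})

test_that("broadband-dominated WAKE carries more sign-pattern entropy
          than delta-dominated NREM", {
  prof <- group_effect_profile()
  hw <- hypnogram(rep("WAKE", 60), epoch_len = 4)
  hn <- hypnogram(rep("NREM", 60), epoch_len = 4)
  ew <- eod_of_pool(pool_state_epochs(simulate_eeg(hw, prof, seed = 63),
                                      hw, "WAKE"), m = 5, tau = 1)
  en <- eod_of_pool(pool_state_epochs(simulate_eeg(hn, prof, seed = 64),
                                      hn, "NREM"), m = 5, tau = 1)
  expect_gt(ew, en)
})

test_that("cohorts have the requested composition and reproduce under
          the master seed", {
  cfg <- simulation_config(n_ac = 7, n_ad = 8, duration = 2 * 3600,
                           seed = 123)
  coh <- simulate_cohort(cfg)
  expect_length(coh$animals, 15)
  grp <- vapply(coh$animals, `[[`, character(1), "group")
  expect_equal(sum(grp == "AC"), 7)
  expect_equal(sum(grp == "AD"), 8)
  for (an in coh$animals) {
    expect_equal(hypnogram_duration(an$hyp_macro), 2 * 3600)
    expect_equal(hypnogram_duration(an$hyp_micro), 2 * 3600)
  }
  coh2 <- simulate_cohort(cfg)
  expect_identical(coh$animals[[5]]$hyp_macro$labels,
                   coh2$animals[[5]]$hyp_macro$labels)
  cfg2 <- simulation_config(n_ac = 7, n_ad = 8, duration = 2 * 3600,
                            seed = 124)
  coh3 <- simulate_cohort(cfg2)
  expect_false(identical(coh$animals[[5]]$hyp_macro$labels,
                         coh3$animals[[5]]$hyp_macro$labels))
})

test_that("an empty group is tolerated by the generator and reported by
          group statistics", {
  cfg <- simulation_config(n_ac = 2, n_ad = 0, duration = 4 * 3600,
                           seed = 9)
  coh <- simulate_cohort(cfg)
  expect_length(coh$animals, 2)
  expect_error(auc_effect(c(1, 2), numeric(0)), "non-empty")
  expect_message(run_macro(coh), "skipped")
})
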