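#' Group effect profile for the synthetic cohort generator
#'
#' Encodes how a group (e.g. a disease strain) deviates from the base
#' semi-Markov sleep model and spectral recipes: multiplicative scaling
#' of mean bout durations, overall transition-rate scaling, per-state
#' relative-power targets, a shift of the broadband-noise fraction that
#' indirectly moves the entropy of difference, and the probability that
#' an animal expresses no REM in a scored phase.
#'
#' @param bout_scale named positive multipliers on mean bout duration,
#'   one per state.
#' @param transition_rate_scale positive multiplier on the overall
#'   transition rate (all mean durations are divided by it).
#' @param relpower named list (per state) of named band fractions
#'   (`delta`, `theta`, `alpha`, `beta`); each set must be nonnegative
#'   and sum to at most 1 -- the remainder is broadband noise.
#' @param eod_shift named per-state shift (on the `[0, 1]` variance
#'   fraction scale) added to `hf_residual`; positive values raise the
#'   state's entropy of difference.
#' @param rem_deficit_prob probability in `[0, 1]` that an animal has no
#'   REM within a scored phase (REM bouts relabelled NREM there).
#' @param emg_amp named per-state EMG amplitude (arbitrary units).
#' @param hf_residual named per-state variance fraction of the
#'   supra-band (31--45 Hz) residual, emulating the fast activity (e.g.
#'   muscle contamination of the WAKE EEG) that survives the analog
#'   30 Hz rolloff.  It is nearly invisible to 1--30 Hz relative power
#'   but governs the sign-pattern entropy at short lags, which is why
#'   `eod_shift` acts through it.
#' @return list of class `group_effect_profile`.
#' @export
group_effect_profile <- function(
    bout_scale = c(WAKE = 1, NREM = 1, REM = 1),
    transition_rate_scale = 1,
    relpower = list(
      WAKE = c(delta = 0.22, theta = 0.30, alpha = 0.10, beta = 0.08),
      NREM = c(delta = 0.62, theta = 0.14, alpha = 0.09, beta = 0.05),
      REM  = c(delta = 0.14, theta = 0.48, alpha = 0.11, beta = 0.09)),
    eod_shift = c(WAKE = 0, NREM = 0, REM = 0),
    rem_deficit_prob = 0,
    emg_amp = c(WAKE = 1.0, NREM = 0.3, REM = 0.1),
    hf_residual = c(WAKE = 0.02, NREM = 0.001, REM = 0.008)) {
  stopifnot(all(VIGILANCE_STATES %in% names(bout_scale)),
            all(VIGILANCE_STATES %in% names(relpower)),
            all(VIGILANCE_STATES %in% names(eod_shift)),
            all(VIGILANCE_STATES %in% names(emg_amp)),
            all(VIGILANCE_STATES %in% names(hf_residual)))
  if (any(bout_scale <= 0) || transition_rate_scale <= 0) {
    stop("all multipliers must be > 0", call. = FALSE)
  }
  for (s in VIGILANCE_STATES) {
    rp <- relpower[[s]]
    if (any(rp < 0) || sum(rp) > 1 + 1e-9) {
      stop("relative-power targets for ", s,
           " must be nonnegative and sum to <= 1", call. = FALSE)
    }
  }
  if (rem_deficit_prob < 0 || rem_deficit_prob > 1) {
    stop("rem_deficit_prob must be in [0, 1]", call. = FALSE)
  }
  structure(list(bout_scale = bout_scale[VIGILANCE_STATES],
                 transition_rate_scale = transition_rate_scale,
                 relpower = relpower[VIGILANCE_STATES],
                 eod_shift = eod_shift[VIGILANCE_STATES],
                 rem_deficit_prob = rem_deficit_prob,
                 emg_amp = emg_amp[VIGILANCE_STATES],
                 hf_residual = hf_residual[VIGILANCE_STATES]),
            class = "group_effect_profile")
}

#' Default aged-control (AC) profile
#' @return a [group_effect_profile()] with neutral multipliers.
#' @export
default_profile_ac <- function() {
  group_effect_profile(rem_deficit_prob = 0.15)
}

#' Default disease (AD-like) profile
#'
#' Emulates the prodromal phenotype: shorter NREM/REM bouts and more
#' sleep/wake transitions, a flatter relative spectrum (less delta, more
#' power in higher frequencies), a lower-entropy WAKE EEG with a
#' higher-entropy NREM EEG, and a higher chance of REM-free scored
#' phases.
#' @return a [group_effect_profile()].
#' @export
default_profile_ad <- function() {
  group_effect_profile(
    bout_scale = c(WAKE = 0.8, NREM = 0.6, REM = 0.6),
    transition_rate_scale = 1.3,
    relpower = list(
      WAKE = c(delta = 0.18, theta = 0.32, alpha = 0.11, beta = 0.10),
      NREM = c(delta = 0.52, theta = 0.18, alpha = 0.11, beta = 0.07),
      REM  = c(delta = 0.12, theta = 0.50, alpha = 0.12, beta = 0.10)),
    eod_shift = c(WAKE = -0.012, NREM = 0.007, REM = 0.005),
    rem_deficit_prob = 0.35
  )
}

#' Simulation configuration
#'
#' Study-level settings for the synthetic cohort: 24 h two-EEG +
#' EMG recordings at 200 Hz under a 12:12 light/dark cycle with lights
#' on at 7 am (ZT 0), scored at 10 s (macro) and 4 s (micro) epochs.
#'
#' @param n_ac,n_ad group sizes.
#' @param duration recording length in seconds; must be a positive
#'   multiple of `epoch_len`.
#' @param fs sampling rate, Hz; must exceed twice the highest
#'   synthesized frequency (40 Hz EMG band top).
#' @param epoch_len macro scoring epoch, seconds.
#' @param micro_epoch_len high-resolution scoring epoch, seconds.
#' @param lights_on_clock clock time of lights-on (ZT 0), informational.
#' @param seed master seed; every animal's randomness is derived from
#'   it.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_ac = 7, n_ad = 8, duration = 86400,
                              fs = 200, epoch_len = 10,
                              micro_epoch_len = 4,
                              lights_on_clock = "07:00", seed = 1) {
  if (duration <= 0 || abs(duration / epoch_len -
                           round(duration / epoch_len)) > 1e-9) {
    stop("duration must be a positive multiple of epoch_len",
         call. = FALSE)
  }
  if (fs <= 2 * 40) {
    stop("fs must exceed twice the highest synthesized frequency (40 Hz)",
         call. = FALSE)
  }
  structure(list(n_ac = n_ac, n_ad = n_ad, duration = duration, fs = fs,
                 epoch_len = epoch_len, micro_epoch_len = micro_epoch_len,
                 lights_on_clock = lights_on_clock, seed = seed),
            class = "simulation_config")
}

#' Base semi-Markov parameters of the sleep/wake process
#'
#' Phase-dependent mean bout durations (lognormal, common log-scale SD)
#' and the embedded next-state transition matrix (zero diagonal, rows
#' sum to 1).  Defaults are design choices producing realistic rodent
#' architecture: sleep-dominated inactive phase, wake-dominated active
#' phase, roughly 45/45/10% WAKE/NREM/REM over 24 h, REM entered only
#' from NREM.
#'
#' @param mean_dur_inactive,mean_dur_active named mean bout durations
#'   (seconds) per state.
#' @param sdlog lognormal log-scale SD of bout durations.
#' @param trans 3 x 3 next-state matrix (rows/cols in WAKE, NREM, REM
#'   order); diagonal must be zero and rows must sum to 1.
#' @return list of class `semi_markov_params`.
#' @export
semi_markov_params <- function(
    mean_dur_inactive = c(WAKE = 100, NREM = 220, REM = 100),
    mean_dur_active = c(WAKE = 400, NREM = 150, REM = 80),
    sdlog = 0.8,
    trans = matrix(c(0, 1, 0,
                     0.65, 0, 0.35,
                     0.8, 0.2, 0),
                   nrow = 3, byrow = TRUE,
                   dimnames = list(VIGILANCE_STATES, VIGILANCE_STATES))) {
  if (any(abs(diag(trans)) > 0) ||
      any(abs(rowSums(trans) - 1) > 1e-9) || any(trans < 0)) {
    stop("transition matrix rows must sum to 1 with a zero diagonal",
         call. = FALSE)
  }
  structure(list(mean_dur = list(inactive = mean_dur_inactive,
                                 active = mean_dur_active),
                 sdlog = sdlog, trans = trans),
            class = "semi_markov_params")
}

# Draw the continuous-time bout sequence of the phase-modulated
# semi-Markov chain; parameters (durations) follow the phase of the
# bout's start.
simulate_bout_sequence <- function(duration, profile, base, zt_start = 0,
                                   init_state = "WAKE") {
  states <- character(0); starts <- numeric(0); durs <- numeric(0)
  t <- 0; s <- init_state
  scale_all <- 1 / profile$transition_rate_scale
  while (t < duration) {
    phase <- if (((zt_start + t) %% SECONDS_PER_DAY) <
                 SECONDS_PER_HALF_DAY) "inactive" else "active"
    mu <- base$mean_dur[[phase]][[s]] * profile$bout_scale[[s]] * scale_all
    d <- rlnorm(1, meanlog = log(mu) - base$sdlog^2 / 2,
                sdlog = base$sdlog)
    d <- min(d, duration - t)
    states <- c(states, s); starts <- c(starts, t); durs <- c(durs, d)
    t <- t + d
    nxt <- base$trans[s, ]
    s <- sample(VIGILANCE_STATES, 1L, prob = nxt)
  }
  data.frame(state = states, start = starts, duration = durs,
             stringsAsFactors = FALSE)
}

# Label each epoch by the state occupying its midpoint.
bouts_to_hypnogram <- function(bseq, duration, epoch_len, zt_start = 0) {
  n_ep <- as.integer(round(duration / epoch_len))
  mid <- (seq_len(n_ep) - 0.5) * epoch_len
  idx <- findInterval(mid, bseq$start)
  hypnogram(bseq$state[idx], epoch_len = epoch_len, zt_start = zt_start)
}

#' Simulate a ground-truth hypnogram
#'
#' Draws one realization of the phase-modulated semi-Markov sleep/wake
#' process: bout durations are lognormal with per-state means (scaled by
#' the profile), the next state follows the embedded transition matrix,
#' and epochs are labelled by the state occupying their midpoint.
#'
#' @param duration recording length, seconds.
#' @param profile a [group_effect_profile()].
#' @param base a [semi_markov_params()].
#' @param epoch_len epoch length in seconds.
#' @param zt_start ZT of the recording start, seconds.
#' @param seed optional seed (deterministic output under a fixed seed).
#' @return a [hypnogram()].
#' @export
simulate_hypnogram <- function(duration = 86400,
                               profile = group_effect_profile(),
                               base = semi_markov_params(),
                               epoch_len = 10, zt_start = 0,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bseq <- simulate_bout_sequence(duration, profile, base, zt_start)
  bouts_to_hypnogram(bseq, duration, epoch_len, zt_start)
}

SYNTH_BANDS <- list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 14),
                    beta = c(14, 30))

# Gaussian noise with a piecewise-flat spectrum: white noise is shaped
# in the frequency domain so that each half-open region [lo, hi) of
# `regions` carries exactly `powers[r]` of variance (other frequencies
# are zeroed).  Synthesis runs on the next power-of-2 length and is
# truncated to n, so realized band energies are exact up to truncation
# leakage.
shaped_noise <- function(n, regions, powers, fs) {
  n2 <- 2^ceiling(log2(max(n, 64)))
  X <- fft(rnorm(n2))
  f <- (seq_len(n2) - 1) * fs / n2
  f_fold <- pmin(f, fs - f)
  Y <- complex(length.out = n2)
  for (r in seq_along(regions)) {
    idx <- which(f_fold >= regions[[r]][1] & f_fold < regions[[r]][2])
    e <- sum(Mod(X[idx])^2) / n2^2
    if (e > 0 && powers[r] > 0) {
      Y[idx] <- X[idx] * sqrt(powers[r] / e)
    }
  }
  Re(fft(Y, inverse = TRUE))[seq_len(n)] / n2
}

# Resolve the per-state spectral regions and their variances: the four
# analysis bands (each holding its relative-power target plus the
# broadband background's bandwidth-proportional share) and the
# supra-band residual that carries the EoD shift.
state_recipe <- function(profile, state) {
  targets <- profile$relpower[[state]]
  r <- max(1 - sum(targets), 0.02)
  targets <- targets * (1 - r) / sum(targets)
  resid <- min(max(profile$hf_residual[[state]] +
                     profile$eod_shift[[state]], 5e-4), 0.2)
  bw <- vapply(SYNTH_BANDS, function(b) b[2] - b[1], 0)
  in_band <- (targets + r * bw / sum(bw)) * (1 - resid)
  list(regions = c(SYNTH_BANDS, list(resid = c(31, 45))),
       powers = c(in_band, resid))
}

#' Synthesize EEG/EMG from a hypnogram
#'
#' Generates state-dependent signals on the hypnogram's grid: each EEG
#' channel is a sum of band-limited noise oscillators (delta-dominant
#' NREM, theta-dominant WAKE/REM) plus a broadband 1--30 Hz background,
#' with component powers set so the realized relative band powers match
#' the profile's targets, and a small supra-band (31--45 Hz) residual
#' emulating fast activity that survives the analog rolloff; the EMG is
#' amplitude-modulated 10--40 Hz noise, high in WAKE, low in NREM,
#' minimal in REM.  Channels thereby follow the acquisition passbands
#' (EEG 1--30 Hz, EMG 10--40 Hz), dominated by in-band power.
#'
#' @param hyp a [hypnogram()] (the truth labels).
#' @param profile a [group_effect_profile()].
#' @param fs sampling rate, Hz; `epoch_len * fs` must be an integer.
#' @param window optional ZT window `c(lo, hi)` (seconds); only this
#'   part of the recording is synthesized (the returned recording's
#'   `zt_start` is the window start).
#' @param channels channel roles to synthesize.
#' @param amp_jitter_sd log-scale SD of the per-epoch EEG amplitude
#'   jitter.
#' @param seed optional seed.
#' @return an [recording()].
#' @export
simulate_eeg <- function(hyp, profile, fs = 200, window = NULL,
                         channels = c("EEG_rostral", "EEG_caudal", "EMG"),
                         amp_jitter_sd = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  spe <- hyp$epoch_len * fs
  if (abs(spe - round(spe)) > 1e-9) {
    stop("hypnogram epoch length and fs mismatch: epoch_len * fs must ",
         "be an integer", call. = FALSE)
  }
  spe <- as.integer(round(spe))
  sub <- if (is.null(window)) hyp else window_hypnogram(hyp, window)
  runs <- rle(sub$labels)
  n_total <- length(sub$labels) * spe
  out <- lapply(channels, function(ch) numeric(n_total))
  names(out) <- channels
  emg_band <- c(10, 40)
  pos <- 0L
  for (k in seq_along(runs$values)) {
    st <- runs$values[k]
    n_ep <- runs$lengths[k]
    n <- n_ep * spe
    rng <- (pos + 1L):(pos + n)
    jit <- rep(rlnorm(n_ep, 0, amp_jitter_sd), each = spe)
    recipe <- state_recipe(profile, st)
    for (ch in channels) {
      if (ch == "EMG") {
        ejit <- rep(rlnorm(n_ep, 0, 0.15), each = spe)
        out[[ch]][rng] <- profile$emg_amp[[st]] * ejit *
          shaped_noise(n, list(emg_band), 1, fs)
      } else {
        out[[ch]][rng] <- jit *
          shaped_noise(n, recipe$regions, recipe$powers, fs)
      }
    }
    pos <- pos + n
  }
  recording(out, fs = fs, zt_start = sub$zt_start)
}

# Animal-level biological variability around a group profile.
jitter_profile <- function(profile, bout_sd = 0.15, relpower_sd = 0.02,
                           emg_sd = 0.1) {
  p <- profile
  p$bout_scale <- p$bout_scale * rlnorm(3, 0, bout_sd)
  p$relpower <- lapply(p$relpower, function(rp) {
    rp <- pmax(rp + rnorm(length(rp), 0, relpower_sd), 0.01)
    if (sum(rp) > 0.95) rp <- rp * 0.95 / sum(rp)
    rp
  })
  p$emg_amp <- p$emg_amp * rlnorm(3, 0, emg_sd)
  p$hf_residual <- pmax((p$hf_residual + p$eod_shift) *
                          rlnorm(3, 0, 0.2), 5e-4)
  p$eod_shift[] <- 0
  p
}

# Relabel REM bouts as NREM within phases hit by the REM deficit.
apply_rem_deficit <- function(bseq, prob, zt_start = 0) {
  phase <- ifelse(((zt_start + bseq$start) %% SECONDS_PER_DAY) <
                    SECONDS_PER_HALF_DAY, "inactive", "active")
  for (ph in c("inactive", "active")) {
    if (runif(1) < prob) {
      bseq$state[bseq$state == "REM" & phase == ph] <- "NREM"
    }
  }
  bseq
}

#' Simulate a two-group cohort
#'
#' Generates `n_ac + n_ad` animals with per-animal seeds derived from
#' the master seed and mild animal-level variability around the group
#' profiles.  Each animal gets a ground-truth bout sequence over the
#' full duration, hypnograms on both the macro (10 s) and micro (4 s)
#' grids, and -- when `eeg_windows` is supplied -- synthesized
#' recordings covering those ZT windows (synthesizing only the analysis
#' windows keeps full-study simulations tractable).
#'
#' @param config a [simulation_config()].
#' @param profile_ac,profile_ad group profiles.
#' @param base a [semi_markov_params()].
#' @param eeg_windows optional list of ZT windows `c(lo, hi)` (seconds)
#'   for which EEG/EMG is synthesized.
#' @param channels channel roles to synthesize.
#' @param write_dir optional directory: hypnogram CSVs (and recording
#'   CSV or EDF files) are written there.
#' @param write_format `"csv"` or `"edf"` for recordings.
#' @return list of class `sim_cohort` with `animals` (each: `id`,
#'   `group`, `hyp_macro`, `hyp_micro`, `recordings` list keyed by
#'   window) and the configuration.
#' @export
simulate_cohort <- function(config = simulation_config(),
                            profile_ac = default_profile_ac(),
                            profile_ad = default_profile_ad(),
                            base = semi_markov_params(),
                            eeg_windows = NULL,
                            channels = c("EEG_rostral", "EEG_caudal",
                                         "EMG"),
                            write_dir = NULL, write_format = "csv") {
  n_total <- config$n_ac + config$n_ad
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, max(n_total, 1L) * 2L)
  groups <- c(rep("AC", config$n_ac), rep("AD", config$n_ad))
  animals <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    grp <- groups[i]
    prof0 <- if (grp == "AC") profile_ac else profile_ad
    set.seed(seeds[2L * i - 1L])
    prof <- jitter_profile(prof0)
    bseq <- simulate_bout_sequence(config$duration, prof, base)
    bseq <- apply_rem_deficit(bseq, prof0$rem_deficit_prob)
    hyp_macro <- bouts_to_hypnogram(bseq, config$duration,
                                    config$epoch_len)
    hyp_micro <- bouts_to_hypnogram(bseq, config$duration,
                                    config$micro_epoch_len)
    recs <- NULL
    if (!is.null(eeg_windows)) {
      set.seed(seeds[2L * i])
      recs <- lapply(eeg_windows, function(w) {
        simulate_eeg(hyp_micro, prof, fs = config$fs, window = w,
                     channels = channels)
      })
      names(recs) <- vapply(eeg_windows, function(w) {
        sprintf("zt%g-%g", w[1] / 3600, w[2] / 3600)
      }, character(1))
    }
    animals[[i]] <- list(id = sprintf("%s%02d", grp, i),
                         group = grp, hyp_macro = hyp_macro,
                         hyp_micro = hyp_micro, recordings = recs)
  }
  cohort <- structure(list(animals = animals, config = config,
                           profile_ac = profile_ac,
                           profile_ad = profile_ad),
                      class = "sim_cohort")
  if (!is.null(write_dir)) write_cohort(cohort, write_dir, write_format)
  cohort
}

#' @export
print.sim_cohort <- function(x, ...) {
  grp <- vapply(x$animals, `[[`, character(1), "group")
  cat(sprintf("<sim_cohort: %d AC + %d AD animals, %.1f h @ %g Hz>\n",
              sum(grp == "AC"), sum(grp == "AD"),
              x$config$duration / 3600, x$config$fs))
  invisible(x)
}

#' Write cohort fixtures to disk
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @param format `"csv"` or `"edf"` for recordings.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = "csv") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (an in cohort$animals) {
    write_hypnogram(an$hyp_macro,
                    file.path(dir, paste0(an$id, "_hyp10.csv")))
    write_hypnogram(an$hyp_micro,
                    file.path(dir, paste0(an$id, "_hyp4.csv")))
    if (!is.null(an$recordings)) {
      for (w in names(an$recordings)) {
        fn <- file.path(dir, paste0(an$id, "_", w,
                                    if (format == "edf") ".edf"
                                    else ".csv"))
        if (format == "edf") write_edf(an$recordings[[w]], fn)
        else write_recording_csv(an$recordings[[w]], fn)
      }
    }
  }
  invisible(dir)
}
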