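# Study-level orchestration: macroarchitecture, microarchitecture and
# group statistics on a cohort (synthetic or assembled from files).

default_windows <- function() list(inactive = c(7, 9) * 3600,
                                   active = c(19, 21) * 3600)

cohort_groups <- function(cohort) {
  vapply(cohort$animals, `[[`, character(1), "group")
}

# Find a recording of an animal covering a ZT window.
window_recording <- function(animal, window) {
  for (rec in animal$recordings) {
    rec_end <- rec$zt_start + n_samples(rec) / rec$fs
    if (rec$zt_start <= window[1] + 1e-9 && rec_end >= window[2] - 1e-9) {
      return(rec)
    }
  }
  NULL
}

#' Sleep macroarchitecture analysis of a cohort
#'
#' Computes, per animal and per group: 2 h-bin state proportions with a
#' two-way (group x time) ANOVA per state; pooled bout-length
#' distributions per state and phase compared by the two-sample
#' Anderson-Darling test; and WAKE/SLEEP transition counts per phase
#' (macro 10 s basis over the full 12 h phases, and micro 4 s basis
#' within the quantitative-EEG windows) compared by AUC with bootstrap
#' CI.  Group statistics are skipped with a message when a group has
#' fewer than two animals.
#'
#' @param cohort a [simulate_cohort()]-shaped cohort.
#' @param bin proportion bin width, seconds.
#' @param windows list of ZT windows for the 4 s-basis transition
#'   counts.
#' @param n_boot,alpha statistical settings.
#' @param seed seed for the bootstrap draws.
#' @return list of class `macro_report`: `proportions`, `anova`,
#'   `bouts`, `bout_tests`, `transitions`, `transition_effects`.
#' @export
run_macro <- function(cohort, bin = 7200, windows = default_windows(),
                      n_boot = 2000, alpha = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grp <- cohort_groups(cohort)
  ids <- vapply(cohort$animals, `[[`, character(1), "id")
  two_groups <- min(table(factor(grp, levels = c("AC", "AD")))) >= 2L

  props <- do.call(rbind, lapply(seq_along(cohort$animals), function(i) {
    p <- state_proportions(cohort$animals[[i]]$hyp_macro, bin = bin)
    cbind(animal = ids[i], group = grp[i], p)
  }))
  anova_res <- NULL
  if (two_groups) {
    anova_res <- lapply(VIGILANCE_STATES, function(s) {
      df <- data.frame(proportion = props[[s]], group = props$group,
                       time = factor(props$bin_start_zt))
      proportions_anova(df)
    })
    names(anova_res) <- VIGILANCE_STATES
  } else {
    message("group statistics skipped: fewer than 2 animals in a group")
  }

  bouts <- do.call(rbind, lapply(seq_along(cohort$animals), function(i) {
    b <- extract_bouts(cohort$animals[[i]]$hyp_macro)
    cbind(animal = ids[i], group = grp[i], b)
  }))
  bout_tests <- NULL
  if (two_groups) {
    bout_tests <- do.call(rbind, lapply(VIGILANCE_STATES, function(s) {
      do.call(rbind, lapply(c("inactive", "active"), function(ph) {
        da <- bouts$duration[bouts$state == s & bouts$phase == ph &
                               bouts$group == "AC"]
        db <- bouts$duration[bouts$state == s & bouts$phase == ph &
                               bouts$group == "AD"]
        if (length(da) < 2L || length(db) < 2L) return(NULL)
        tst <- anderson_darling_2samp(da, db)
        data.frame(state = s, phase = ph, n_ac = length(da),
                   n_ad = length(db), A2 = tst$statistic, p = tst$p,
                   significant = tst$p < alpha)
      }))
    }))
  }

  trans <- do.call(rbind, lapply(seq_along(cohort$animals), function(i) {
    an <- cohort$animals[[i]]
    ph <- split_phase(an$hyp_macro)
    rows <- lapply(c("inactive", "active"), function(p) {
      data.frame(animal = ids[i], group = grp[i], phase = p,
                 basis = "macro",
                 n_transitions = count_transitions(ph[[p]])$n_total)
    })
    if (!is.null(an$hyp_micro)) {
      for (wn in names(windows)) {
        h <- tryCatch(window_hypnogram(an$hyp_micro, windows[[wn]]),
                      error = function(e) NULL)
        if (!is.null(h)) {
          rows[[length(rows) + 1L]] <-
            data.frame(animal = ids[i], group = grp[i], phase = wn,
                       basis = "micro",
                       n_transitions = count_transitions(h)$n_total)
        }
      }
    }
    do.call(rbind, rows)
  }))
  trans_eff <- NULL
  if (two_groups) {
    combos <- unique(trans[, c("phase", "basis")])
    trans_eff <- do.call(rbind, lapply(seq_len(nrow(combos)), function(r) {
      sel <- trans$phase == combos$phase[r] & trans$basis == combos$basis[r]
      a <- trans$n_transitions[sel & trans$group == "AC"]
      b <- trans$n_transitions[sel & trans$group == "AD"]
      es <- bootstrap_auc_ci(a, b, n_boot = n_boot)
      data.frame(phase = combos$phase[r], basis = combos$basis[r],
                 auc = es$auc, ci_low = es$ci_low, ci_high = es$ci_high,
                 significant = es$significant, label = es$label)
    }))
  }

  structure(list(proportions = props, anova = anova_res, bouts = bouts,
                 bout_tests = bout_tests, transitions = trans,
                 transition_effects = trans_eff),
            class = "macro_report")
}

#' Sleep microarchitecture analysis of a cohort
#'
#' For each analysis window and vigilance state: per-animal pooled
#' relative-power spectra with group median and median-absolute-
#' deviation summaries, per-bin AUC with the two-neighboring-bin
#' significance mask, band-power AUC effects, and entropy of difference
#' (per lag) with AC-vs-AD effects per state plus within-group
#' WAKE-vs-NREM effects.  Animals without the state in a window (after
#' the closest-episode REM fallback) are dropped for that state with a
#' logged count.
#'
#' @param cohort a cohort whose animals carry recordings covering the
#'   analysis windows.
#' @param windows named list of ZT windows (seconds).
#' @param config a [spectral_config()].
#' @param channel EEG channel role to analyse.
#' @param m,taus EoD embedding dimension and lags.
#' @param n_boot,seed bootstrap settings.
#' @param max_epochs cap on pooled epochs per animal/state (bounds
#'   runtime; `Inf` uses everything).
#' @return list of class `micro_report`: `spectra` (per window/state:
#'   `freq`, group median/MAD matrices, `mask` data.frame, dropped
#'   counts), `band_effects`, `eod` (per-animal values), `eod_effects`,
#'   `eod_state_contrast`.
#' @export
run_micro <- function(cohort, windows = default_windows(),
                      config = spectral_config(), channel = "EEG_rostral",
                      m = 5, taus = c(1, 6), n_boot = 2000, seed = NULL,
                      max_epochs = Inf) {
  if (!is.null(seed)) set.seed(seed)
  grp <- cohort_groups(cohort)
  ids <- vapply(cohort$animals, `[[`, character(1), "id")
  spectra <- list(); band_effects <- list(); eod_rows <- list()

  for (wn in names(windows)) {
    w <- windows[[wn]]
    for (s in VIGILANCE_STATES) {
      rp <- list(); bp <- list(); keep <- character(0)
      for (i in seq_along(cohort$animals)) {
        an <- cohort$animals[[i]]
        rec <- window_recording(an, w)
        if (is.null(rec)) next
        pool <- pool_state_epochs(rec, an$hyp_micro, s, window = w,
                                  channel = channel,
                                  max_epochs = max_epochs)
        if (is_absent(pool)) next
        sr <- relative_power(welch_psd(pool, config))
        rp[[an$id]] <- sr$power
        bp[[an$id]] <- band_power(sr)
        keep <- c(keep, an$id)
        for (tau in taus) {
          eod_rows[[length(eod_rows) + 1L]] <- data.frame(
            animal = an$id, group = an$group, window = wn, state = s,
            tau = tau,
            eod = eod_of_pool(pool, m = m, tau = tau, normalize = TRUE))
        }
        freq <- sr$freq
      }
      if (length(rp) == 0L) next
      mat <- do.call(rbind, rp)
      g <- grp[match(keep, ids)]
      entry <- list(freq = freq, animals = keep, group = g,
                    power = mat,
                    n_dropped = length(ids) - length(keep))
      if (sum(g == "AC") >= 2L && sum(g == "AD") >= 2L) {
        entry$median_ac <- apply(mat[g == "AC", , drop = FALSE], 2, median)
        entry$mad_ac <- apply(mat[g == "AC", , drop = FALSE], 2, mad)
        entry$median_ad <- apply(mat[g == "AD", , drop = FALSE], 2, median)
        entry$mad_ad <- apply(mat[g == "AD", , drop = FALSE], 2, mad)
        entry$mask <- spectral_auc_mask(mat[g == "AC", , drop = FALSE],
                                        mat[g == "AD", , drop = FALSE],
                                        freq = freq, n_boot = n_boot)
        bmat <- do.call(rbind, bp)
        band_effects[[paste(wn, s, sep = ".")]] <-
          do.call(rbind, lapply(colnames(bmat), function(b) {
            es <- bootstrap_auc_ci(bmat[g == "AC", b], bmat[g == "AD", b],
                                   n_boot = n_boot)
            data.frame(window = wn, state = s, band = b, auc = es$auc,
                       ci_low = es$ci_low, ci_high = es$ci_high,
                       significant = es$significant, label = es$label)
          }))
      }
      spectra[[paste(wn, s, sep = ".")]] <- entry
    }
  }

  eod <- do.call(rbind, eod_rows)
  eod_effects <- NULL; eod_contrast <- NULL
  if (!is.null(eod)) {
    combos <- unique(eod[, c("window", "state", "tau")])
    eod_effects <- do.call(rbind, lapply(seq_len(nrow(combos)),
                                         function(r) {
      sel <- eod$window == combos$window[r] &
        eod$state == combos$state[r] & eod$tau == combos$tau[r]
      a <- eod$eod[sel & eod$group == "AC"]
      b <- eod$eod[sel & eod$group == "AD"]
      if (length(a) < 2L || length(b) < 2L) return(NULL)
      es <- bootstrap_auc_ci(a, b, n_boot = n_boot)
      cbind(combos[r, ], auc = es$auc, ci_low = es$ci_low,
            ci_high = es$ci_high, significant = es$significant)
    }))
    cc <- expand.grid(window = unique(eod$window), tau = taus,
                      group = c("AC", "AD"), stringsAsFactors = FALSE)
    eod_contrast <- do.call(rbind, lapply(seq_len(nrow(cc)), function(r) {
      sel <- eod$window == cc$window[r] & eod$tau == cc$tau[r] &
        eod$group == cc$group[r]
      wv <- eod$eod[sel & eod$state == "WAKE"]
      nv <- eod$eod[sel & eod$state == "NREM"]
      if (length(wv) < 2L || length(nv) < 2L) return(NULL)
      es <- bootstrap_auc_ci(wv, nv, n_boot = n_boot)
      cbind(cc[r, ], auc = es$auc, ci_low = es$ci_low,
            ci_high = es$ci_high, significant = es$significant)
    }))
  }
  structure(list(spectra = spectra,
                 band_effects = do.call(rbind, band_effects),
                 eod = eod, eod_effects = eod_effects,
                 eod_state_contrast = eod_contrast),
            class = "micro_report")
}

#' Run the full analysis pipeline
#'
#' Macro- and microarchitecture analyses on one cohort; optionally
#' writes all tabular outputs as CSV plus a run log (seed and settings)
#' to a directory.  Outputs are deterministic under a fixed seed.
#'
#' @param cohort the cohort to analyse.
#' @param out_dir optional output directory.
#' @inheritParams run_macro
#' @inheritParams run_micro
#' @return list with `macro` and `micro` reports.
#' @export
run_all <- function(cohort, windows = default_windows(),
                    config = spectral_config(), n_boot = 2000,
                    seed = 1, out_dir = NULL, max_epochs = Inf) {
  macro <- run_macro(cohort, windows = windows, n_boot = n_boot,
                     seed = seed)
  has_rec <- any(!vapply(cohort$animals, function(a)
    is.null(a$recordings), logical(1)))
  micro <- if (has_rec) {
    run_micro(cohort, windows = windows, config = config,
              n_boot = n_boot, seed = seed + 1L, max_epochs = max_epochs)
  } else NULL
  res <- list(macro = macro, micro = micro)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, name) {
      if (!is.null(df)) write.csv(df, file.path(out_dir,
                                                paste0(name, ".csv")),
                                  row.names = FALSE)
    }
    wr(macro$proportions, "proportions")
    wr(macro$bouts, "bouts")
    wr(macro$bout_tests, "bout_tests")
    wr(macro$transitions, "transitions")
    wr(macro$transition_effects, "transition_effects")
    if (!is.null(micro)) {
      wr(micro$band_effects, "band_effects")
      wr(micro$eod, "eod")
      wr(micro$eod_effects, "eod_effects")
      wr(micro$eod_state_contrast, "eod_state_contrast")
    }
    writeLines(c(sprintf("seed: %d", seed),
                 sprintf("n_boot: %d", n_boot),
                 sprintf("generated: %s", format(Sys.time()))),
               file.path(out_dir, "run_log.txt"))
  }
  res
}

#' Read a study configuration from YAML
#'
#' Required fields: `n_ac`, `n_ad`, `duration`, `fs`, `seed`; optional:
#' `epoch_len`, `micro_epoch_len`, `n_boot`, `alpha`, `windows` (list
#' of `[lo, hi]` ZT hours).  A missing required field raises an error
#' naming it.
#'
#' @param path YAML file path.
#' @return list with `config` (a [simulation_config()]), `windows`,
#'   `n_boot`, `alpha`.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  for (f in c("n_ac", "n_ad", "duration", "fs", "seed")) {
    if (is.null(y[[f]])) {
      stop("study config is missing required field '", f, "'",
           call. = FALSE)
    }
  }
  cfg <- simulation_config(n_ac = y$n_ac, n_ad = y$n_ad,
                           duration = y$duration, fs = y$fs,
                           epoch_len = y$epoch_len %||% 10,
                           micro_epoch_len = y$micro_epoch_len %||% 4,
                           seed = y$seed)
  windows <- if (!is.null(y$windows)) {
    lapply(y$windows, function(w) as.numeric(w) * 3600)
  } else default_windows()
  list(config = cfg, windows = windows, n_boot = y$n_boot %||% 2000,
       alpha = y$alpha %||% 0.05)
}
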