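#' AUC effect size between two groups
#'
#' Mann-Whitney pair-counting estimator of the probability that a value
#' drawn from group B exceeds a value drawn from group A, with ties
#' counted half: `(wins + 0.5 * ties) / (nA * nB)`.  Orientation is
#' fixed: AUC > 0.5 means group B is stochastically larger.  0.5 means
#' no effect; effect magnitude is symmetric under mirroring
#' (`1 - AUC`).
#'
#' @param a,b numeric vectors (non-empty).
#' @return AUC point estimate in `[0, 1]`.
#' @examples
#' auc_effect(c(1, 3), c(2, 4)) # 0.75
#' @export
auc_effect <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  (sum(outer(b, a, ">")) + 0.5 * sum(outer(b, a, "=="))) /
    (length(a) * length(b))
}

#' Qualitative label for an AUC effect magnitude
#'
#' Effects are classified on the mirrored magnitude
#' `max(AUC, 1 - AUC)`: `>= 0.9` excellent/outstanding, `>= 0.8`
#' good/excellent, `>= 0.7` fair/acceptable, `>= 0.6` poor, otherwise
#' none (an AUC of 0.15 therefore maps to magnitude 0.85, a good
#' effect).
#'
#' @param auc AUC point estimate.
#' @return list with `magnitude` and `label`.
#' @export
auc_magnitude <- function(auc) {
  mag <- max(auc, 1 - auc)
  label <- if (mag >= 0.9) "excellent/outstanding"
  else if (mag >= 0.8) "good/excellent"
  else if (mag >= 0.7) "fair/acceptable"
  else if (mag >= 0.6) "poor"
  else "none"
  list(magnitude = mag, label = label)
}

# Stratified bootstrap resamples of the AUC.  For small groups the
# nA x nB pair comparisons are vectorized across all resamples at once;
# larger groups fall back to a per-resample rank computation.
boot_auc_draws <- function(a, b, n_boot) {
  nA <- length(a); nB <- length(b)
  amat <- matrix(a[sample.int(nA, nA * n_boot, replace = TRUE)], nrow = nA)
  bmat <- matrix(b[sample.int(nB, nB * n_boot, replace = TRUE)], nrow = nB)
  if (nA * nB <= 2500L) {
    wins <- numeric(n_boot)
    for (i in seq_len(nA)) {
      ai <- amat[i, ]
      for (j in seq_len(nB)) {
        bj <- bmat[j, ]
        wins <- wins + (bj > ai) + 0.5 * (bj == ai)
      }
    }
    wins / (nA * nB)
  } else {
    vapply(seq_len(n_boot), function(k) {
      r <- rank(c(amat[, k], bmat[, k]))
      (sum(r[(nA + 1L):(nA + nB)]) - nB * (nB + 1) / 2) / (nA * nB)
    }, numeric(1))
  }
}

#' Bootstrap confidence interval for the AUC effect size
#'
#' Stratified percentile bootstrap: values are resampled with
#' replacement within each group, the AUC recomputed per resample, and
#' the CI taken from the percentiles of the resampled distribution.
#' The effect is significant when the CI excludes 0.5.  Degenerate
#' resamples (a single distinct value in both groups) evaluate to 0.5
#' through the tie rule.
#'
#' @param a,b numeric vectors with at least 2 values each.
#' @param n_boot number of bootstrap resamples (default 10000).
#' @param conf confidence level (default 0.95).
#' @param seed optional integer seed for the resampling.
#' @return object of class `effect_size`: `auc`, `ci_low`, `ci_high`,
#'   `n_boot`, `significant`, `magnitude`, `label`.
#' @export
bootstrap_auc_ci <- function(a, b, n_boot = 10000, conf = 0.95,
                             seed = NULL) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("need at least 2 values per group", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  auc <- auc_effect(a, b)
  draws <- boot_auc_draws(a, b, n_boot)
  alpha <- (1 - conf) / 2
  ci <- unname(quantile(draws, c(alpha, 1 - alpha)))
  ci[1] <- min(ci[1], auc); ci[2] <- max(ci[2], auc)
  mag <- auc_magnitude(auc)
  structure(list(auc = auc, ci_low = ci[1], ci_high = ci[2],
                 n_boot = n_boot,
                 significant = ci[1] > 0.5 || ci[2] < 0.5,
                 magnitude = mag$magnitude, label = mag$label),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("AUC = %.3f [%.3f-%.3f]%s (%s)\n", x$auc, x$ci_low,
              x$ci_high, if (x$significant) " *" else "", x$label))
  invisible(x)
}

#' Per-frequency-bin AUC with the two-neighboring-bin rule
#'
#' Computes the AUC effect size (with bootstrap CI) between two groups
#' at every frequency bin of their relative-power spectra, then masks
#' the per-bin significances so that a bin is reported significant only
#' if it and at least one adjacent bin are individually significant --
#' the multiplicity control used for spectral comparisons.
#'
#' @param spectra_a,spectra_b matrices of per-animal spectra (one row
#'   per animal, one column per frequency bin) on a common grid.
#' @param freq optional vector of bin frequencies (Hz).
#' @param n_boot,conf,seed bootstrap settings as in
#'   [bootstrap_auc_ci()].
#' @return data.frame with one row per bin: `freq`, `auc`, `ci_low`,
#'   `ci_high`, `significant` (per-bin), `masked` (after the neighbor
#'   rule; always a subset of `significant`, in runs of length >= 2).
#' @export
spectral_auc_mask <- function(spectra_a, spectra_b, freq = NULL,
                              n_boot = 2000, conf = 0.95, seed = NULL) {
  spectra_a <- as.matrix(spectra_a); spectra_b <- as.matrix(spectra_b)
  if (ncol(spectra_a) != ncol(spectra_b)) {
    stop("spectra are on different frequency grids", call. = FALSE)
  }
  if (!is.null(freq) && length(freq) != ncol(spectra_a)) {
    stop("freq length must match the number of bins", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  nb <- ncol(spectra_a)
  res <- lapply(seq_len(nb), function(j) {
    bootstrap_auc_ci(spectra_a[, j], spectra_b[, j], n_boot = n_boot,
                     conf = conf)
  })
  sig <- vapply(res, `[[`, logical(1), "significant")
  nbr <- c(sig[-1], FALSE) | c(FALSE, sig[-nb])
  data.frame(
    freq = freq %||% seq_len(nb),
    auc = vapply(res, `[[`, numeric(1), "auc"),
    ci_low = vapply(res, `[[`, numeric(1), "ci_low"),
    ci_high = vapply(res, `[[`, numeric(1), "ci_high"),
    significant = sig,
    masked = sig & nbr
  )
}

# --- two-sample Anderson-Darling (Scholz-Stephens), ties-adjusted ----

ad_stat_2samp <- function(a, b) {
  x <- c(a, b)
  n <- c(length(a), length(b))
  N <- sum(n)
  z <- sort(unique(x))
  l <- as.numeric(table(match(x, z)))           # multiplicities
  Bj <- cumsum(l) - l / 2                        # B~_j
  inner <- 0
  for (i in 1:2) {
    xi <- if (i == 1) a else b
    fij <- as.numeric(table(factor(match(xi, z), levels = seq_along(z))))
    Mij <- cumsum(fij) - fij / 2                 # M~_ij
    denom <- Bj * (N - Bj) - N * l / 4
    keep <- denom > 0
    inner <- inner + (1 / n[i]) *
      sum((l[keep] / N) * (N * Mij[keep] - n[i] * Bj[keep])^2 /
            denom[keep])
  }
  (N - 1) / N * inner
}

ad_sigma <- function(n, k = 2) {
  N <- sum(n)
  H <- sum(1 / n)
  h <- sum(1 / seq_len(N - 1))
  i <- seq_len(N - 2)
  g <- sum((1 / (N - i)) * (cumsum(1 / seq_len(N - 1))[N - 1] -
                              cumsum(1 / seq_len(N - 1))[i]))
  a <- (4 * g - 6) * (k - 1) + (10 - 6 * g) * H
  b <- (2 * g - 4) * k^2 + 8 * h * k +
    (2 * g - 14 * h - 4) * H - 8 * h + 4 * g - 6
  cc <- (6 * h + 2 * g - 2) * k^2 + (4 * h - 4 * g + 6) * k +
    (2 * h - 6) * H + 4 * h
  d <- (2 * h + 6) * k^2 - 4 * h * k
  v <- (a * N^3 + b * N^2 + cc * N + d) /
    ((N - 1) * (N - 2) * (N - 3))
  sqrt(v)
}

# Interpolated upper-tail p for the standardized statistic T, k = 2
# (m = k - 1 = 1): critical values t_m(alpha) = b0 + b1/sqrt(m) + b2/m.
ad_pvalue_interp <- function(tstat, m = 1) {
  alpha <- c(0.25, 0.10, 0.05, 0.025, 0.01)
  b0 <- c(0.675, 1.281, 1.645, 1.960, 2.326)
  b1 <- c(-0.245, 0.250, 0.678, 1.149, 1.822)
  b2 <- c(-0.105, -0.305, -0.362, -0.391, -0.396)
  tm <- b0 + b1 / sqrt(m) + b2 / m
  f <- splinefun(tm, log(alpha / (1 - alpha)), method = "natural")
  p <- 1 / (1 + exp(-f(tstat)))
  min(max(p, 1e-10), 1)
}

#' Two-sample Anderson-Darling test
#'
#' Scholz-Stephens k-sample Anderson-Darling statistic (k = 2,
#' ties-adjusted midrank version) for the null hypothesis that two
#' samples share one continuous distribution -- the test used to compare
#' bout-length distributions between groups.  The p-value comes from the
#' published interpolation of the standardized statistic; a label
#' permutation fallback gives exact Monte-Carlo p-values for small
#' samples.
#'
#' @param a,b numeric samples with at least 2 observations each.
#' @param method `"asymptotic"` (default; permutation is used
#'   automatically below 5 observations per group) or `"permutation"`.
#' @param n_perm permutation count for the fallback.
#' @param seed optional seed for the permutation draw.
#' @return list of class `ad_test`: `statistic` (A2), `tstat`
#'   (standardized), `p`, `method`, `n`.
#' @export
anderson_darling_2samp <- function(a, b,
                                   method = c("asymptotic", "permutation"),
                                   n_perm = 1999, seed = NULL) {
  method <- match.arg(method)
  if (length(a) < 2L || length(b) < 2L) {
    stop("need at least 2 observations per group", call. = FALSE)
  }
  if (method == "asymptotic" && min(length(a), length(b)) < 5L) {
    method <- "permutation"
  }
  obs <- ad_stat_2samp(a, b)
  sig <- ad_sigma(c(length(a), length(b)))
  tstat <- (obs - 1) / sig
  if (method == "asymptotic") {
    p <- ad_pvalue_interp(tstat)
  } else {
    if (!is.null(seed)) set.seed(seed)
    pool <- c(a, b)
    nA <- length(a)
    cnt <- 0L
    for (i in seq_len(n_perm)) {
      idx <- sample.int(length(pool), nA)
      if (ad_stat_2samp(pool[idx], pool[-idx]) >= obs - 1e-12) {
        cnt <- cnt + 1L
      }
    }
    p <- (1 + cnt) / (n_perm + 1)
  }
  structure(list(statistic = obs, tstat = tstat, p = p, method = method,
                 n = c(length(a), length(b))),
            class = "ad_test")
}

#' @export
print.ad_test <- function(x, ...) {
  cat(sprintf("Anderson-Darling 2-sample: A2 = %.3f, T = %.3f, p = %.4g (%s)\n",
              x$statistic, x$tstat, x$p, x$method))
  invisible(x)
}

#' Dunn-Sidak adjusted significance level
#'
#' Familywise error control for `k` comparisons:
#' `alpha' = 1 - (1 - alpha)^(1/k)`.
#'
#' @param alpha familywise level.
#' @param k number of comparisons.
#' @return per-comparison level.
#' @export
sidak_alpha <- function(alpha, k) 1 - (1 - alpha)^(1 / k)

#' Two-way ANOVA on state proportions with Dunn-Sidak post-hoc
#'
#' Standard two-factor (group x time bin) ANOVA with interaction on
#' per-animal state proportions, followed by per-bin group comparisons
#' (Welch t-tests) at the Dunn-Sidak adjusted level.
#'
#' @param data data.frame with at least the response and two factor
#'   columns.
#' @param response,group,time column names.
#' @param alpha familywise level for the post-hoc comparisons.
#' @return list of class `proportions_anova`: `table` (data.frame with
#'   `term`, `df`, `F`, `p`), `posthoc` (per time level: `diff`,
#'   `p_raw`, `p_sidak`), `alpha_sidak`.
#' @export
proportions_anova <- function(data, response = "proportion",
                              group = "group", time = "time",
                              alpha = 0.05) {
  g <- factor(data[[group]]); tm <- factor(data[[time]])
  if (nlevels(g) < 2L || nlevels(tm) < 2L) {
    stop("both factors need at least 2 levels", call. = FALSE)
  }
  y <- data[[response]]
  fit <- aov(y ~ g * tm)
  at <- anova(fit)
  tab <- data.frame(term = c(group, time,
                             paste0(group, ":", time), "Residuals"),
                    df = at$Df, F = at$`F value`, p = at$`Pr(>F)`)
  lv <- levels(tm); k <- length(lv)
  ph <- do.call(rbind, lapply(lv, function(l) {
    ya <- y[tm == l & g == levels(g)[1]]
    yb <- y[tm == l & g == levels(g)[2]]
    if (length(ya) < 2L || length(yb) < 2L ||
        (sd(ya) == 0 && sd(yb) == 0)) {
      return(data.frame(time = l, diff = mean(yb) - mean(ya),
                        p_raw = NA_real_, p_sidak = NA_real_))
    }
    tt <- t.test(yb, ya)
    data.frame(time = l, diff = unname(diff(rev(tt$estimate))),
               p_raw = tt$p.value,
               p_sidak = 1 - (1 - tt$p.value)^k)
  }))
  structure(list(table = tab, posthoc = ph,
                 alpha_sidak = sidak_alpha(alpha, k)),
            class = "proportions_anova")
}

#' @export
print.proportions_anova <- function(x, ...) {
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Chi-squared test on 2 x 2 group composition counts
#'
#' Compares category counts (e.g. females/males) between two groups;
#' because the use of a continuity correction is a genuine analysis
#' choice for small tables, both the corrected and uncorrected
#' statistics are reported side by side.
#'
#' @param counts_a,counts_b length-2 nonnegative integer vectors.
#' @return list with `statistic`, `p` (uncorrected), `statistic_yates`,
#'   `p_yates`, and the `table`.
#' @export
chisq_counts <- function(counts_a, counts_b) {
  tab <- rbind(counts_a, counts_b)
  if (any(tab < 0) || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("counts must be nonnegative with no zero marginal",
         call. = FALSE)
  }
  plain <- suppressWarnings(chisq.test(tab, correct = FALSE))
  yates <- suppressWarnings(chisq.test(tab, correct = TRUE))
  list(statistic = unname(plain$statistic), p = plain$p.value,
       statistic_yates = unname(yates$statistic), p_yates = yates$p.value,
       table = tab)
}

#' Grubbs outlier test (iterative)
#'
#' One-at-a-time two-sided Grubbs test under approximate normality:
#' the most extreme value is tested against the t-based critical value
#' and, if rejected at `alpha`, removed; the procedure repeats on the
#' remainder.
#'
#' @param x numeric vector, `n >= 3`, non-constant.
#' @param alpha significance level per step.
#' @return integer indices (into `x`) of flagged outliers (possibly
#'   empty).
#' @export
grubbs_test <- function(x, alpha = 0.05) {
  if (length(x) < 3L) stop("Grubbs test needs n >= 3", call. = FALSE)
  if (sd(x) == 0) stop("constant series", call. = FALSE)
  idx <- seq_along(x)
  out <- integer(0)
  repeat {
    n <- length(idx)
    if (n < 3L || sd(x[idx]) == 0) break
    g <- abs(x[idx] - mean(x[idx])) / sd(x[idx])
    i_max <- which.max(g)
    tc <- qt(1 - alpha / (2 * n), n - 2)
    g_crit <- ((n - 1) / sqrt(n)) * sqrt(tc^2 / (n - 2 + tc^2))
    if (g[i_max] > g_crit) {
      out <- c(out, idx[i_max])
      idx <- idx[-i_max]
    } else break
  }
  sort(out)
}
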