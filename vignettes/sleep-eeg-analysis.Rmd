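---
title: "Sleep macro- and microarchitecture analysis with sleeparch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sleep macro- and microarchitecture analysis with sleeparch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleeparch)
```

## What the package models

`sleeparch` analyses rodent polysomnography — two epidural EEG leads
(rostral and caudal) plus a nuchal EMG, sampled at 200 Hz with the EEG
band-limited to 1–30 Hz and the EMG to 10–40 Hz — on two levels:

* **Macroarchitecture**: epoch-wise vigilance states (WAKE, NREM, REM;
  10 s epochs for whole-day scoring, 4 s for high-resolution segments)
  summarised as per-bin state proportions, bout-length distributions,
  and WAKE↔SLEEP transition counts (NREM and REM merged into SLEEP, so
  alternations within sleep are not transitions).
* **Microarchitecture**: within-state EEG content via Welch relative
  power spectra and the *entropy of difference* (EoD), the Shannon
  entropy of the distribution of sign patterns of lagged amplitude
  differences.

Group comparisons run through a common statistical layer: the
Mann–Whitney AUC effect size with stratified percentile-bootstrap 95%
confidence intervals (significant when the CI excludes 0.5), the
two-sample Anderson–Darling test for bout-length distributions, a
two-way group × time ANOVA with Dunn–Šidák post-hoc comparisons for
state proportions, chi-squared for group composition, and an iterative
Grubbs screen for outliers.

Because studies of this kind rarely deposit raw recordings, the package
ships a first-class synthetic cohort generator so every stage can be
exercised, calibrated, and regression-tested against known ground
truth.

## Entropy of difference

For a series $x_1, \dots, x_n$, embedding dimension $m$ and lag $\tau$,
motif $i$ is $(x_i, x_{i+\tau}, \dots, x_{i+(m-1)\tau})$ and its
pattern is the sign of each of the $m-1$ consecutive within-motif
differences; there are $n - (m-1)\tau$ motifs and $2^{m-1}$ possible
patterns. The EoD is the base-2 Shannon entropy of the empirical
pattern distribution; with `normalize = TRUE` it is divided by its
$(m-1)$-bit maximum so that values lie in $[0, 1]$ and are comparable
across lags. A strictly monotone series produces a single pattern and
EoD exactly 0; i.i.d. noise approaches the maximum.

```{r eod}
x <- c(5, 4, 6, 2, 3, 1)
sign_motifs(x, m = 3, tau = 1)
entropy_of_difference(x, m = 3, tau = 1, normalize = FALSE)  # 1 bit
permutation_entropy(x, m = 3, tau = 1)                       # 1.5 bits
```

Defaults follow the analysis design: $m = 5$, $\tau = 1$ for fast
dynamics and $\tau = 6$ for slow dynamics. Exact zero differences are
mapped to "−" (`merge_down`); band-passed EEG essentially never ties,
but digitized fixtures can, and a deterministic documented rule is
required. A `third_symbol` policy (ternary patterns) is available for
sensitivity analysis. In pooled per-state computations motifs never
cross epoch boundaries (pooled epochs are not temporally contiguous);
pattern *counts* are pooled across epochs before the entropy is taken.

EoD is invariant under strictly increasing amplitude transforms and, on
every input, equals an exhaustive enumeration oracle — both are part of
the test suite.

## Spectral analysis

Welch PSDs use NFFT = 256 at 200 Hz (resolution $200/256 = 0.78125$
Hz), Hamming-windowed 256-sample segments with 50% overlap inside each
4 s epoch, averaged over all epochs in a pool. Relative power divides
each bin by the summed absolute power between 1 and 30 Hz; band powers
sum bins whose centers lie in half-open intervals delta [1, 4), theta
[4, 8), alpha [8, 14), beta [14, 30) Hz, which partition the
normalization band exactly. The lower delta edge reflects the 1 Hz
acquisition high-pass and the beta ceiling the 30 Hz low-pass; rat band
edges are a package choice since conventions vary.

Two normalization conventions exist in the literature; the package
defaults to *pool-then-normalize* (`relative_power()`) and also offers
*per-epoch* normalization (`relative_power_per_epoch()`), which weights
every epoch equally instead of by its power.

Per-state pooling takes the epochs of one state inside an analysis
window (defaults ZT 7–9 h and ZT 19–21 h, i.e. mid-inactive and
mid-active). If a window contains no REM, the temporally closest REM
episode in the same light/dark phase is substituted; when the whole
phase lacks REM the animal receives an explicit absent-state marker and
is dropped from REM group statistics with a logged count — REM-free
scored phases are a real feature of aged cohorts that the generator
reproduces (`rem_deficit_prob`).

Spectral group comparisons are computed per frequency bin and reported
significant only when the bootstrap CI excludes 0.5 at **two or more
neighbouring bins** (`spectral_auc_mask()`); this neighbour rule is the
only multiplicity control applied across bins, by design.

## The synthetic cohort generator

The generator *defines* the study conditions; its defaults are fixed
design choices, not tuning knobs.

**Hypnograms** follow a phase-modulated semi-Markov chain: per-state
lognormal bout durations (log-scale SD 0.8, chosen for the heavy right
tail that makes empirical bout ECDFs approach 1 gradually) with
phase-dependent means — inactive phase WAKE/NREM/REM 100/220/100 s,
active 400/150/80 s — and an embedded next-state matrix in which REM is
entered only from NREM (W→N 1; N→W 0.65, N→R 0.35; R→W 0.8, R→N 0.2).
Long-run occupancy is ≈47/45/8% WAKE/NREM/REM over 24 h, a realistic
aged-rat architecture; the suite checks the simulated proportions
against a brute-force renewal-theory oracle. Group profiles scale mean
bout durations per state (`bout_scale`) and the overall transition rate
(`transition_rate_scale`); epochs are labelled by the state occupying
their midpoint, on both the 10 s and 4 s grids from the same underlying
bout sequence.

**EEG** is synthesised per bout as Gaussian noise with a piecewise-flat
spectrum: the four analysis bands carry the profile's relative-power
targets (plus the broadband remainder's bandwidth-proportional share),
so the realized relative band powers measured by the spectral module
match the targets by construction (closed-loop tested to ±0.05). Band
energies are set exactly in the frequency domain — one FFT pair per
bout and channel — rather than by time-domain filtering, which would
leak power across band edges.

A small supra-band **31–45 Hz residual** (≈2% of variance in WAKE,
≈0.1% in NREM, ≈0.8% in REM by default) emulates the fast activity,
such as waking muscle contamination, that survives a gradual analog
30 Hz rolloff. This residual is nearly invisible to 1–30 Hz relative
power but dominates the lag-1 sign-difference statistics, because
differencing weights spectral content by $\sin^2(\pi f / f_s)$. It is
therefore the mechanism behind `eod_shift`: within a linear Gaussian
model the in-band spectrum alone cannot move EoD and band powers
independently — in particular it cannot produce a group with *more*
relative beta power yet *less* WAKE entropy — whereas the residual
decouples the two. The broadband background is flat in 1–30 Hz (not
1/f) so this bookkeeping stays exact.

**EMG** is amplitude-modulated 10–40 Hz noise (state amplitudes
1.0/0.3/0.1 for WAKE/NREM/REM) with per-epoch lognormal jitter.
Animal-level variability multiplies bout scales (log-SD 0.15), perturbs
band targets (SD 0.02), and jitters EMG amplitudes and the residual
fraction, so group statistics face realistic between-animal spread.

What the generator does **not** emulate: non-Gaussian waveforms
(spindles, K-complex-like transients, theta sawtooth asymmetry),
artifacts (movement, electrode pop), circadian drift within phases, and
any biophysical network structure. Passing tests therefore demonstrate
correctness of the analysis machinery and sensible behaviour under a
plausible statistical model of the data — not performance on real
recordings.

## The threshold scorer

The semi-automated 4 s scorer is a transparent three-rule classifier on
per-epoch features (Welch band powers per EEG channel, theta/delta
ratio, EMG RMS):

1. EMG RMS above the WAKE threshold → WAKE (muscle tone dominates);
2. otherwise theta/delta above 2.0 → REM;
3. otherwise NREM;

followed by a smoothing pass absorbing single-epoch islands into the
preceding bout (a 1-epoch window deliberately leaves the short bouts
that fragmentation analyses study untouched), then any manual overrides
— making the scorer semi-automated. Calibration is per-recording: the
WAKE threshold defaults to the geometric midpoint of the 10th and 95th
EMG RMS percentiles, which lands in the amplitude gap between atonic
sleep and waking tone for any realistic wake/sleep mixture; a fixed
percentile rule (60th) is available but is only appropriate when wake
occupies roughly 40–50% of the scored segment. Against generator truth
the scorer reaches Cohen's kappa ≥ 0.9 on default profiles; the suite
regression-tests kappa ≥ 0.8. Users with real data can quantify scorer
error the same way, which is why truth hypnograms are first-class
outputs.

## Numerical and statistical choices

* **Bootstrap AUC**: stratified (within-group) resampling, percentile
  CI, default 10,000 resamples (1,000–2,000 in the large simulation
  loops); degenerate resamples with a single distinct value in both
  groups count as AUC 0.5 through the tie rule. Null calibration at
  group sizes 7 vs 8 gives a 5–6% rejection rate at the nominal 5%.
  Effect magnitudes are mirrored (`max(AUC, 1-AUC)`) and labelled:
  ≥0.9 excellent/outstanding, ≥0.8 good/excellent, ≥0.7
  fair/acceptable, ≥0.6 poor.
* **Anderson–Darling**: ties-adjusted Scholz–Stephens statistic;
  p-values by natural-spline interpolation of the published critical
  points of the standardized statistic (exact at the 5% point), with a
  label-permutation fallback used automatically below 5 observations
  per group. With durations discretized to a 10 s grid the heavy ties
  inflate the type-I rate to ≈7.5% at n = 100 per group; calibration
  statements refer to continuous bout-length models.
* **ANOVA**: independent-cell two-way decomposition (group × time bin)
  with interaction; per-bin Welch t post-hoc at the Šidák-adjusted
  level $1-(1-\alpha)^{1/k}$. Treating per-animal bins as independent
  cells ignores the repeated-measures structure; this matches common
  practice for these designs and is a documented limitation.
* **Quantiles**: bout-length percentile readouts (e.g. the "80% of
  bouts shorter than" corridor) use type-7 linear interpolation.
* **Phase convention**: ZT 0 = lights-on = start of the inactive
  phase; epochs are half-open `[start, start + len)` intervals and an
  epoch is inactive iff its start lies in ZT `[0, 12 h)` mod 24 h. A
  bout spanning the boundary belongs to the phase of its first epoch
  (a deterministic rule affecting at most a couple of bouts per
  phase). Bouts truncated by the recording edges are included by
  default (`drop_boundary = FALSE`).
* **Degenerate inputs**: empty bout sets return an explicit
  empty-distribution object; absent-REM animals return markers rather
  than errors; zero-power spectra, constant EMG, empty groups, and
  misaligned epoch grids raise informative errors.

## Problem sizes used by the checks

The shipped verification runs are sized to be reproducible on a single
CPU in minutes, as a deliberate package choice: null calibrations use
1,000 replicates (group sizes 7 vs 8, 2,000 bootstrap resamples);
phenotype-recovery runs 50 cohorts of 7 + 8 animals with full 24 h
hypnograms, EEG synthesised for a 30-minute inactive-phase window, at
most 50 pooled epochs per animal and state, and 1,000 resamples per
CI; the scorer check uses 4 animals × 6 h segments. Enlarging any of
these only tightens the Monte-Carlo error of the reported rates.

## Known limitations

* The generator is linear and Gaussian; EoD differences arise purely
  from spectral shape (including the supra-band residual), not from
  waveform nonlinearity as in real EEG.
* The rostral and caudal leads are treated as independent realizations
  of the same state recipe; no volume-conduction correlation is
  modelled, and anatomical labels are opaque strings.
* The EDF support is a minimal continuous-recording reader/writer
  (16-bit, one sampling rate), not a general EDF(+) implementation.
* Asymptotic Anderson–Darling p-values are interpolated and least
  accurate far from conventional significance levels; use the
  permutation method when exactness matters.
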