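Package: sleeparch
Title: Sleep Architecture and EEG Microarchitecture Analysis for Rodent Polysomnography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of rodent sleep macro- and microarchitecture from
    EEG/EMG recordings: epoch-based hypnogram metrics (state proportions,
    bout-length distributions, sleep/wake transitions), Welch power
    spectral density with relative band power, sign-pattern entropy of
    difference and permutation entropy, and a statistical layer built on
    AUC effect sizes with bootstrap confidence intervals, the two-sample
    Anderson-Darling test, two-way ANOVA with Dunn-Sidak post-hoc
    comparisons, and Grubbs outlier screening. Includes a semi-Markov
    synthetic cohort generator so the full pipeline can be exercised and
    calibrated without animal recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
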