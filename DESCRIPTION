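Package: circaphase
Title: Circadian Phase Estimation from Minute-Level Physiological Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates individual circadian phase from minute-resolution
    wearable and ingestible-sensor recordings collected during daily routine.
    Implements two-harmonic (24 h + 12 h) cosinor regression with residual
    bootstrap confidence intervals for acrophase and bathyphase, dim light
    melatonin onset (DLMO) from evening salivary profiles with individual or
    pooled baseline thresholds and a light-exposure validity rule, a
    three-state harmonic hidden Markov model for actigraphy yielding the
    center-of-rest time, and the INTime multivariate predictor of core body
    temperature bathyphase selected by stepwise AICc regression. A synthetic
    cohort generator with known ground-truth phases supports end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
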