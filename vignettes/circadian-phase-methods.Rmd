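---
title: "Estimating circadian phase from daily-routine recordings"
author: "circaphase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating circadian phase from daily-routine recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circaphase)
```

## The problem

The clock time at which core body temperature (CBT) reaches its daily
minimum — the *bathyphase* — is the standard reference marker for an
individual's circadian phase, but measuring it directly requires either a
constant-routine laboratory protocol or days of continuous gut-temperature
telemetry from ingestible pills. `circaphase` implements a pipeline that
estimates the CBT bathyphase noninvasively from quantities that can be
collected during a person's ordinary daily routine: sex, the
morningness–eveningness questionnaire (MEQ) chronotype score, the
center-of-rest time computed from chest-worn actigraphy, and the bathyphase
of chest *surface* temperature. The multivariate predictor built from these
four covariates is referred to as the INTime model.

Because the underlying cohort recordings are not publicly deposited, the
package ships a synthetic-data generator that reproduces the statistical
structure of such a study — it is first-class, tested code, and every
downstream stage is validated against its known ground truth.

## Phase representation

All phase markers are clock times. Nocturnal phases (CBT bathyphase
≈ 03:30, center-of-rest ≈ 03:05) sit next to the midnight wrap, so the
package stores phases on the unwrapped window [12, 36) anchored at the
prior noon: 03:30 becomes 27.5 while 17:40 stays 17.667. Regression over
phases then never straddles a wrap point. Daytime chest bathyphases
(~11:00–15:00) are unwrapped around their own cluster center (11 h) by
`unwrap_to()`. Circular arithmetic (`circular_distance()`,
`circular_diff()`, `circular_mean_hours()`) is used whenever two phases are
compared, so all distances are at most 12 h regardless of representation.

## Preprocessing

Raw series are minute-level. The chain follows the field's convention for
pill and chest-patch thermometry:

1. **Ingestion artifact removal** — within the first 3 h of each pill
   segment, samples outside [35, 40] °C are deleted (food and drink
   transiently distort the reading). The window and range are
   configurable; 3 h and [35, 40] °C are deliberately conservative.
2. **Pill stitching** — the first pill's record is used until its
   elimination; the second pill (swallowed ~24 h later) continues the
   series from that instant, its overlap discarded.
3. **5-minute aggregation** — left-closed clock-aligned bins.
4. **1-hour centred moving average** — the window is [t − 30 min,
   t + 30 min), i.e. 12 bins on a full 5-min grid; edges and gaps average
   whatever samples are present. Smoothing before profile averaging
   follows the order in which a practitioner applies these steps to a
   continuous record.
5. **Averaged 24-h profile** — bins pooled by minute-of-day across days;
   empty bins are flagged `NA`, never zero-filled.

## Two-harmonic cosinor

The average day oscillation of core and chest temperature is modelled as

y(t) = M + a1·cos(2πt/T1) + b1·sin(2πt/T1) + a2·cos(2πt/T2) + b2·sin(2πt/T2) + e(t)

with fixed periods T1 = 12 h and T2 = 24 h, estimated by ordinary least
squares. The acrophase and bathyphase are the argmax/argmin of the fitted
curve on a 1-minute grid (the native device resolution), ties broken
toward the earlier clock time. With a zero harmonic amplitude the phases
are undefined and flagged, never silently zero.

90% CIs come from a residual bootstrap: residuals are resampled i.i.d.
onto the fitted values and the model refit (1000 trials by default). Since
the design is fixed, all replicates reduce to matrix products, so even
1000 trials are inexpensive. The CI is the central-mass quantile interval
of the signed circular differences from the point estimate, re-centered on
it — this avoids wrap artifacts and guarantees the estimate lies inside
its own interval. Whether the original study resampled residuals, cases or
blocks is not documented; the residual scheme is this package's choice and
is stated as such.

A structural feature worth knowing: when the 12-h component's trough
coincides with the 24-h trough (as it does for gut temperature), the
fitted minimum is sharp while the maximum flattens or splits. Bathyphase
CIs are therefore systematically narrower than acrophase CIs — the reason
the pipeline predicts the bathyphase rather than the acrophase.

**Dominant-period classification.** The original spectral-resampling
approach is replaced by a simpler, fully specified surrogate: the fitted
harmonic amplitude at 24 h and 12 h is compared against a permutation null
obtained by independently circular-shifting each recorded day (which
destroys day-to-day phase alignment but preserves within-day structure).
A period is called significant at α = 0.01 (per period, 99 permutations;
two periods are screened, keeping the family false-alarm rate on
arrhythmic records near 2%). The dominant period is the significant one
with the larger amplitude, else `none`.

## DLMO

Dim light melatonin onset is the first strict upward crossing of a
threshold by the evening salivary concentration profile, linearly
interpolated between the bracketing samples. The threshold is the mean of
3 consecutive pre-rise baseline values plus twice their sample SD; when a
subject lacks an adequate baseline, a pooled threshold (mean + 2 SD of the
baseline values pooled across subjects that do have one) is used instead.
Samples are invalid if any lux reading above 50 occurred in the 30 min
before collection (half-open window, strict 50-lux exceedance).

"Before rise" is not operationally defined in the literature this follows;
the package uses the three *earliest* consecutive valid samples and
requires no internal rise (no sample above 1.5× the running mean of its
predecessors within the triple). The triple is not allowed to slide later:
for a subject whose onset precedes the first sample, the saturated
post-rise plateau is locally flat and would masquerade as a baseline. This
restrictive rule is why a substantial minority of subjects fall back to
the pooled threshold, mirroring the ~40% individual-baseline availability
seen in field cohorts.

## Rest-activity harmonic HMM

Activity counts are log(1+x)-transformed and modelled by a 3-state hidden
Markov model — inactive/rest, moderately active, highly active — with
Gaussian emissions per state and *time-inhomogeneous* transitions: each
row of transition logits is a baseline plus sine/cosine pairs at the 24-h
period (one harmonic by default) evaluated at the clock time of the
current minute. Estimation is EM; the E-step (forward–backward, compiled)
marginalises missing minutes, and the transition M-step is a weighted
multinomial logistic fit with analytic gradients on expected transition
counts collapsed by minute-of-day. Five seeded random restarts guard
against local maxima by default (fewer in the test suite); states are
relabelled by ascending emission mean, so state 1 is always rest. The
published formulation this emulates is not reproduced verbatim — harmonics
could equally sit on emissions or the initial law — and the choice of
transition-logit harmonics is documented here as this package's.

The **center-of-rest** time is the gravity center of the rest-state
posterior probability profile over the 1440 minutes of the day, computed
*circularly* (resultant-vector angle, minute bins weighted at their
midpoints): rest spans straddle midnight for most subjects, where a linear
centroid would be badly wrong.

## The INTime model

Candidate predictors (sex, age, BMI, chronotype score, DLMO,
center-of-rest, chest acrophase and bathyphase) are first screened by
pairwise Spearman correlations and two-sample t-tests (possible effects
flagged at p < 0.1). The model itself is selected by bidirectional
stepwise search minimising AICc, starting from the full model. Because
AICc values are only comparable on a common data set, candidate moves are
scored on the complete cases of the full candidate set; the selected model
is then refit on the complete cases of its own covariates, so subjects
missing DLMO are retained whenever DLMO is not selected. How the original
analysis handled this is unstated; this two-stage rule is the package's
documented choice.

The published instance of the model is

> CBT bathyphase = 1.33·sex − 0.058·chronotype + 0.472·center-of-rest − 0.145·chest bathyphase

(sex coded 1 = male, phases in decimal hours, no intercept).
`published_intime()` carries these coefficients verbatim and immutably.
`fit_intime()` includes an intercept by default — standard regression
practice, and the printed equation cannot reproduce a cohort centered near
03:30 without one, suggesting an absorbed constant; the discrepancy is
deliberate and surfaced here. Prediction bands for fitted models use the
usual t-quantile × predictive-SE construction; the published instance
stores no residual variance and yields point predictions only.

Two behaviours of stepwise AICc deserve honesty. First, like all
AIC-family criteria it admits a spurious covariate at roughly the
χ²(1) > 2 rate (~16% per candidate), so with four noise candidates the
probability of recovering *exactly* the generating covariate set is only
about 0.84⁴ ≈ 0.5 even at n = 200 — coefficient estimates for the true
covariates remain accurate regardless. Second, on pure noise the expected
selected size is ~1, not 0. Both are properties of the criterion, not
defects of the implementation, and the test suite asserts the rates theory
predicts.

**Sample-size stability.** Pseudo-datasets of arbitrary size n are built
by resampling covariate rows with replacement and adding resampled
residuals to the fitted values; refitting gives a Monte-Carlo distribution
of adjusted R², whose central 90%/95% quantile intervals shrink roughly as
1/√n. The reported requirement is the smallest n whose interval width
drops below 10% of the reference adjusted R².

## The synthetic cohort generator

`generate_cohort()` draws, per subject, a latent circadian-lateness factor
z ~ N(0,1) that drives every phase truth, so that the chronotype score
(negatively) and the phase markers (positively) are mutually correlated at
the strength seen in field cohorts (score ↔ center-of-rest rank
correlation ≈ −0.7). The true CBT bathyphase is computed from the
published coefficients plus a calibration intercept of 19.14 h — chosen
once so the cohort median lands at 03:30 — and Gaussian noise with SD
0.8 h, the residual spread implied by published field-cohort accuracy
summaries (error IQR of roughly −40 to +31 min and ~79% of subjects
within 1 h correspond to a residual SD near 0.8 h, as does an adjusted
R² near 0.64). Signal structure:

* **Core temperature**: mesor ~37 °C, 24-h amplitude 0.2–0.4 °C, 12-h
  amplitude 0.05–0.15 °C with both troughs aligned at the true bathyphase
  (producing the sharp-minimum/flat-maximum asymmetry); white noise SD
  0.1 °C; two pill segments starting 24 h apart with log-normal durations
  clipped to 0.2–13.4 days; ingestion artifacts (values outside
  35–40 °C) at 15%/min over the first 2 h of each segment.
* **Chest surface temperature**: dominant-period class drawn with
  probabilities 0.636/0.273/0.091 for 24-h/12-h/arrhythmic; dominant
  amplitude 0.8–1.2 °C, minor 0.1–0.3 °C, noise SD 0.3 °C.
* **Activity**: three regimes with negative-binomial counts (means 2, 35,
  180 counts/min — overdispersed, with excursions into the hundreds); the
  rest regime concentrates in a rest span of mean duration 8 h centered on
  the true center-of-rest; ~2% of minutes removed as device-removal gaps.
  The count law is a documented convenience: any overdispersed law with
  well-separated regimes would do.
* **Melatonin**: flat baseline 0.5–2.0 pg/mL before the true DLMO, then a
  saturating logistic rise of 8–20 pg/mL (scale 0.5 h); assay noise SD
  0.05 pg/mL (~5% CV); a configurable fraction of samples receives a
  >50-lux burst within the preceding 30 min. The baseline spread must be
  wide relative to assay noise for the pooled mean+2SD threshold to clear
  every subject's own baseline — with within-assay noise comparable to the
  between-subject spread the pooled method misfires by construction, which
  constrains realistic calibrations.

Everything is driven by deterministic per-subject substreams: subject i's
record depends only on (seed, i), so cohorts are bit-reproducible and
extendable without disturbing earlier subjects.

What the generator does **not** emulate: sleep architecture,
thermoregulatory transients (exercise, showers), masking of temperature by
activity, food-intake melatonin contamination, non-24-h free-running
periods, or assay nonlinearity. Passing parameter-recovery tests on this
generator therefore demonstrates correctness of the estimators under the
assumed signal model, not robustness to every artifact of real wearables.

## Numerical choices and problem sizes

* Extrema on a 1-min grid; ties toward the earlier time. Amplitudes below
  1e-9 (relative to the mesor) are treated as zero and phases flagged.
* EM convergence: relative log-likelihood change < 1e-6, max 50
  iterations; emission SDs floored at 0.05 on the log scale; likelihood
  monotonicity is asserted in tests to 1e-8 relative tolerance.
* The exact-inference oracle for the HMM enumerates all 3^12 state paths
  of 12-step chains; forward–backward must agree to 1e-9.
* Test-suite problem sizes are chosen for a desk run: 500 simulated
  subjects for bootstrap coverage (200 bootstrap trials each), 100
  subjects for center-of-rest recovery (4 recording days, 2 EM restarts),
  100 replicates of n = 200 for selection recovery, cohorts of 16–33 for
  the end-to-end checks. The analysis scripts use the full study-scale
  settings (n = 33, 7-day chest records, 1000 bootstrap trials).

## Known limitations

* The pooled-threshold DLMO can misfire for subjects whose baseline sits
  at the top of the cohort distribution if assay noise is large relative
  to the between-subject baseline spread; this is a property of the
  mean+2SD pooled rule itself.
* The dominant-period permutation test assumes day-to-day phase
  stability; a drifting (non-24-h) rhythm would be classified as weak or
  arrhythmic.
* `published_intime()` predictions are on the phase coding used here
  (center-of-rest unwrapped near 27, chest bathyphase near 11); applying
  them to phases coded differently shifts predictions by a constant.
* Stepwise-AICc exact-set recovery is capped near 50–60% by the
  criterion's over-selection rate, as discussed above.
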