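# circaphase

Estimating an individual's circadian phase from minute-level physiological
recordings made during ordinary daily routine — and predicting the core
body temperature (CBT) bathyphase, the reference circadian phase marker,
from noninvasive surrogates.

Circadian timing of treatment (chronotherapy) needs a per-patient phase
estimate, but the gold-standard markers are burdensome: CBT telemetry
requires ingestible pills, and salivary dim light melatonin onset (DLMO)
requires a controlled dim-light evening. `circaphase` implements a
complete pipeline around the INTime regression model, which predicts the
CBT bathyphase from two time-invariant covariates (sex, chronotype score)
and two markers computable from a chest sensor worn during daily life
(actigraphy center-of-rest time, chest surface temperature bathyphase):

> bathyphase = 1.33·sex − 0.058·MEQ score + 0.472·center-of-rest − 0.145·chest bathyphase
> (sex: 1 = male, 0 = female; phases in decimal hours)

## What is implemented

* **Domain types** — unit-tagged minute-level time series; clock phases on
  an unwrapped [12, 36) window so nocturnal phases never straddle the
  midnight wrap; Horne–Östberg chronotype categories.
* **Synthetic cohort generator** — subjects with known ground-truth
  phases driven by a latent circadian-lateness factor: two pill segments
  with ingestion artifacts and transit-limited durations, 7-day chest
  temperature and 3-regime activity with device-removal gaps, evening
  melatonin profiles with light contamination. Bit-reproducible per
  (seed, subject).
* **Preprocessing** — artifact deletion, pill stitching, 5-min
  aggregation, centred 1-h moving average, averaged 24-h profiles, lagged
  pill-overlap correlation.
* **Rhythm analysis** — two-harmonic (12 h + 24 h) cosinor by OLS;
  acrophase/bathyphase on a 1-min grid; 90% circular CIs by residual
  bootstrap (1000 trials); dominant-period classification against a
  per-day circular-shift permutation null.
* **DLMO** — 50-lux/30-min sample validity rule, individual mean+2SD
  baseline threshold with pooled-threshold fallback, interpolated first
  upward crossing.
* **Rest-activity HMM** — 3-state hidden Markov model with Gaussian
  emissions on log-counts and 24-h harmonic transition logits, fit by EM
  (compiled forward–backward); center-of-rest as the circular gravity
  center of the rest-state posterior profile.
* **INTime** — Spearman/t-test covariate screen, bidirectional stepwise
  AICc selection, the published fixed-coefficient equation, 90%
  prediction bands, accuracy summaries, and residual-bootstrap
  sample-size stability of the adjusted R².

## Worked example

```r
library(circaphase)

res <- run_pipeline(run_config(n = 33, seed = 149, n_boot = 1000))
res$model
#> INTime bathyphase model (stepwise AICc)
#> selected: sex, center_of_rest
#>    (Intercept)            sex center_of_rest
#>         4.9585         1.1581         0.8139
#> adjusted R^2 = 0.566, residual SD = 0.879 h, n = 33
res$accuracy$median_min       # median signed error, minutes:  7.34
res$accuracy$fraction_lt_1h   # subjects with |error| < 1 h:   0.758
res$accuracy$band_coverage    # 90% prediction bands:          0.939
```

The numbers mean: on a simulated 33-subject cohort the stepwise-selected
model explains ~57% of the bathyphase variance (adjusted), within-sample
predictions land within an hour of the measured bathyphase for ~76% of
subjects (median error ~7 min), and the 90% prediction bands cover ~94%
of measured values. At n = 33 the selected covariate subset varies
between cohort draws — here the chronotype and chest-temperature terms
were absorbed by the correlated center-of-rest covariate — which is
exactly the small-sample instability the sample-size analysis
(`analysis/05_sample_size.R`) quantifies.

The `analysis/` directory holds the same workflow as numbered narrative
scripts (simulate → preprocess → phase estimates → INTime model →
sample-size stability), each writing its tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_preprocess.R
Rscript analysis/03_phase_estimates.R
Rscript analysis/04_intime_model.R
Rscript analysis/05_sample_size.R
```

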