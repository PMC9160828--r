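# rtmseeg

Predicting response to repetitive transcranial magnetic stimulation (rTMS)
from resting-state EEG, for the hardest realistic setting: a cohort of 14
Alzheimer's patients, 8 responders (TMS+) and 6 non-responders (TMS-),
labeled by whether their Mini-Mental State Examination score declined over
the treatment course (ties count as benefit), against tens of thousands of
spectral features.

The package implements the full analysis pipeline and the machinery needed
to trust it at this sample size:

- **Windowed band-power features.** Each channel is band-limited into the
  canonical EEG bands (delta 0.5–4, theta 4–7, alpha 7.5–13, beta 15–28,
  gamma 29–48 Hz) by FFT masking, and the feature per (channel, band) is
  the series of mean squared amplitudes in non-overlapping 2-s windows —
  the temporal power profile, not just its scalar mean.
- **Feature-selection routes** compared under one engine: none, PCA,
  Daubechies-4 wavelet coefficient selection, stepwise linear discriminant
  analysis (SWLDA), linear-SVM weight ranking, and restriction to a single
  band.
- **Classifier.** A soft-margin SVM with the Gaussian kernel
  `K(x,x') = exp(-||x-x'||²/(2σ²))`; the dual is solved in-package by a
  compact SMO verified against libsvm and an exhaustive QP oracle, and the
  decision function `f(x) = Σ α_m y_m K(x, x_m) + b` is evaluated
  explicitly. SWLDA doubles as a linear classifier baseline.
- **Balanced Monte-Carlo leave-one-out validation.** Hold out one subject;
  repeatedly draw a maximal class-balanced subset of the rest, split it
  into balanced train/validation sets, fit everything on training rows
  only, and average over `min(choose(max, max−min) × partitions, 50)`
  trials per fold. No leakage, no silent fold drops, bit-identical under a
  fixed seed.
- **Interval-shrinking hyperparameter search** over (C, σ) on a log scale,
  with exhaustive grid search as the oracle and fallback.
- **A synthetic EEG generator** (1/f background + band-limited components,
  spatial mixing, per-subject gain variability, MMSE tables consistent
  with the labeling rule) whose defaults implant a theta amplitude gain
  ratio of 1.5 between classes — the positive control — or nothing — the
  null control.

## Worked example

```r
library(rtmseeg)

cfg <- synthetic_config(seed = 20260401)   # 14 subjects, theta ratio 1.5
features <- cohort_features(cfg)           # filter, epoch, reject, extract
dim(features$X)
#> [1]    14 14700                          # 30 ch x 5 bands x 98 windows

theta <- mc_leave_one_out(features, selector = "band_restrict",
                          selector_params = list(band = "theta"),
                          seed = 20260401)
theta
#> <validation_report> mc_leave_one_out: overall 92.3% (sd 26.7 over 700 trials)

none <- mc_leave_one_out(features, selector = "none", seed = 20260401)
none$overall
#> [1] 76.28571
```

Restricting to the band that actually carries the class difference lifts
leave-one-out accuracy from 76.3% to 92.3% on this cohort — the engine
recovers the implanted effect, and (run `analysis/02_selector_comparison.R`)
the same pipeline on a null cohort with no class difference stays inside
the 14-subject chance band.

The numbered scripts under `analysis/` are the full study: `01_simulate.R`
(cohort, subject table, feature matrix), `02_selector_comparison.R` (all
selection routes, positive and null cohorts), `03_window_sweep.R` (1/2/4-s
feature windows), `04_band_weights.R` (cumulative linear-SVM band weights
and SWLDA selections), `05_validation_curves.R` (training/validation size
sweeps and the direct 9-of-14 train/test protocol). Each writes its tables
under `results/`.

## Documentation

The methods vignette (`vignettes/methods.Rmd`) describes the model and its
assumptions, every tunable parameter with its default and rationale, what
the synthetic generator does and does not emulate, and the numerical
choices (filter design, wavelet boundary handling, solver tolerances,
tie-breaking) in detail.
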