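---
title: "Predicting rTMS response from EEG band power: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting rTMS response from EEG band power: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Repetitive transcranial magnetic stimulation (rTMS) helps some Alzheimer's
patients and not others, and nothing in the usual clinical covariates
predicts who will benefit. This package implements a complete analysis
pipeline for asking whether resting-state EEG can: subjects are labeled
responders (TMS+) or non-responders (TMS-) by the change in their
Mini-Mental State Examination score across the treatment course (a
non-decrease counts as benefit, so ties go to TMS+), and a classifier is
trained to predict that label from spectral features of the EEG.

Two things make this statistically treacherous: the cohorts are tiny
(14 subjects, 8 responders / 6 non-responders) and unbalanced, while the
feature space is enormous (tens of thousands of band-power values). The
pipeline therefore couples the feature representation to a balanced
Monte-Carlo leave-one-out engine designed for exactly this regime, and the
package ships a synthetic EEG generator with a known, controllable class
effect so that every stage can be validated end to end: a positive control
(the pipeline must recover an implanted band effect) and a null control
(it must fall to chance when the effect is absent).

## Feature representation

Each recording is band-pass filtered (0.1-60 Hz, zero-phase order-4
Butterworth sections) with a 50 Hz notch (second-order, Q = 30), cut into
1-s epochs, and cleaned by amplitude-threshold rejection (default
±100 µV). The kept epochs are concatenated and, per channel, band-limited
into the five canonical EEG bands by Fourier masking — FFT bins outside the
band are zeroed and the signal inverse-transformed. Band edges follow the
convention delta 0.5-4, theta 4-7, alpha 7.5-13, beta 15-28, gamma
29-48 Hz; the gaps between printed edges belong to no band and are never
closed.

The feature for a (channel, band) pair is not the single scalar band power
but the series of mean squared amplitudes in consecutive non-overlapping
2-s windows. This keeps temporal structure and, crucially, the
multi-source organisation of the data: transforms never cross channel
boundaries, and the provenance index maps every flattened feature back to
its (channel, band, window). `scalar_band_power()` provides the scalar
baseline for comparison; the analysis scripts show it against the windowed
representation.

Two numerical notes. First, "power of the filtered signal in a window"
computed in the time domain agrees with the direct frequency-domain
band-bin sum by Parseval's theorem; the test suite holds the two routes
against each other at 1e-6 relative. Second, the band-limiting FFT is
applied to the whole-window prefix of the concatenated signal (the
trailing partial window contributes no features anyway), which keeps the
transform length a highly composite number — mixed-radix FFTs degrade
badly on lengths with large prime factors.

## Preprocessing stands in for a manual workflow

The reference workflow this automates involved manual epoch review and
ICA blink correction by a single operator. Neither is reproducible in
software, so the package uses a deterministic amplitude-threshold rule;
the synthetic data contains no blink artifacts, only occasional
large-amplitude excursions, which the threshold handles. The zero-phase
filtering applies each filter in its own forward-backward pass, notch
first: a 0.1 Hz high-pass has a settling mode of several seconds, and
running the notch after it would pass that edge transient through. The
line through each channel's endpoints is subtracted before filtering and
restored scaled by the cascade's DC gain, which removes the edge-padding
artifacts that otherwise dominate a low-cutoff high-pass on finite
records. The Butterworth design is built as second-order sections because
the equivalent single transfer function is numerically unusable at a
0.1 Hz cutoff with 500 Hz sampling.

## Feature-selection routes

Five routes are compared under the identical validation engine, every one
fitted on training rows only and applied unchanged to held-out rows:

* **none** — the full feature vector.
* **pca** — principal components of the training covariance (default 20,
  capped by the training row count).
* **wavelet** — each (channel, band) window series is transformed by an
  orthonormal Daubechies-4 wavelet decomposition; coefficient positions
  are ranked by mean absolute value over training rows and the global top
  10% kept. Periodized boundary handling was chosen over symmetric
  extension: it keeps the transform exactly orthonormal, so perfect
  reconstruction and energy bookkeeping are exact rather than approximate,
  and selection by coefficient magnitude is selection by energy. The
  decomposition depth is the number of factors of two in the block length,
  capped by the 8-tap filter support.
* **swlda** — stepwise linear discriminant analysis: forward inclusion of
  the feature with the smallest regression p-value (threshold 0.10),
  backward removal above 0.15, the standard stepwise convention; at most
  as many features as training samples, the rank limit of the
  least-squares system. The fitted discriminant doubles as the linear
  classifier baseline.
* **band restriction** — keep one band's features only (theta in the
  headline configuration), motivated by the weight hierarchy below.

Feature standardization (z-score by training mean and SD, zero-variance
columns pinned to zero) precedes every route; without it, weights across
bands with different power scales are incomparable.

### Reading feature importance from the SVM

The classifier of record is an RBF-kernel SVM, under which primal feature
weights are undefined. Importance is therefore read from a companion
linear-kernel SVM fit on the same standardized training data:
`w = Σ α_m y_m x_m`, with `|w_j|` the importance of feature j and band
importances the sums over member features. This preserves both the
nonlinear classifier and a well-defined weight-reading procedure. The
duplicate-column thought experiment is worth a caution: duplicating a
feature changes the kernel and hence the optimum, so weight is split
across copies symmetrically but their sum is not conserved; the tests
assert the symmetry and check the weight vector against an independent
libsvm fit.

## The classifier

The SVM uses the Gaussian-width convention
`K(x, x') = exp(-||x - x'||² / (2σ²))`. With no values given for the
margin parameters, the defaults are C = 1 and `σ = sqrt(d/2)` for d
standardized features (the common 1/d inverse-scale convention); both are
searchable. The soft-margin dual is solved by a compact SMO
(maximal-violating-pair selection, tolerance 1e-6, deterministic); on the
kernel sizes this engine sees (at most 14 subjects) a fit costs well under
a millisecond, which matters because one full validation run performs
hundreds of fits and the acceptance suite tens of thousands. The solver is
held against two independent oracles in the tests: an exhaustive
active-set enumeration of the dual QP on small problems, and libsvm
(via e1071) on larger ones. Predictions evaluate
`f(x) = Σ α_m y_m K(x, x_m) + b` over the stored support vectors; exact
ties (`f = 0`) go to the majority training class and are recorded as such.

## The validation engine

Plain leave-one-out with 8/6 classes trains on unbalanced sets, which both
destabilizes model selection and biases accuracies. The engine instead:

1. holds out one subject as the test case (every subject exactly once);
2. draws a maximal balanced subset of the remaining 13 — `min(n+, n-)`
   subjects per class, sampled without replacement;
3. partitions it into a balanced training set and a balanced validation
   set (default one subject per class in validation, the rest training);
4. standardizes, selects features, tunes hyperparameters (if enabled) and
   fits on the training rows only;
5. records the test prediction, and repeats from step 2.

The number of Monte-Carlo trials per fold is the count of distinct maximal
balanced subsets, `choose(max, max - min)`, times the number of distinct
train/validation partitions, capped at 50; the cap is what binds at the
study's cohort sizes. Reports carry per-subject and overall mean
accuracies, the across-trial standard deviation, the composition of every
split when auditing is on, and any skipped (infeasible) folds — never
silently dropped. Identical seeds reproduce reports bit for bit.

The simpler direct-classification protocol (stratified train/test split at
a 9-of-14 ratio, 50 random trials, test balanced by subsampling) and
sweeps over training / validation set sizes round out the engine; both are
exercised in the analysis scripts.

## Hyperparameter search

Grid search over (C, σ) is the standard but multiplies the Monte-Carlo
cost. The alternative implemented here is an interval-shrinking search:
evaluate a coarse grid (5 points per axis) over the current interval,
re-center on the best point, shrink interval and step by a factor of 0.5,
and stop when the best validation accuracy fails to improve or after 6
iterations. Both parameters are searched on a log10 scale (C in
[1e-2, 1e3], σ in [1e-2, 1e2]); ties break toward smaller C then smaller
σ, the simpler model. The exhaustive grid is retained as an optional mode
and as the oracle the tests compare against: on concave landscapes the
search must land within one final step of the exhaustive argmax. The
shrink schedule and per-iteration grid density are conventions — the
geometric refinement reaches about 1.5% of the initial interval width —
and are configurable.

## The synthetic cohort generator

Each channel is a sum of 1/f ("pink") background noise and five
band-limited Gaussian components, built directly in the frequency domain —
complex Gaussian coefficients on the band's FFT bins, scaled for unit
time-domain variance — so band confinement is exact by construction and
matches the FFT-mask band definition used downstream. Channels share a
common source (mixing fraction 0.3) so spatial correlation is nontrivial,
and each subject draws one log-normal amplitude multiplier per band
(SD 0.15 on the log scale, shared across channels) as between-subject
biological variability.

The defaults are the study conditions: 8 TMS+ / 6 TMS- subjects,
30 scalp channels at 500 Hz, 4-minute eyes-closed recordings; band
amplitudes 8 µV RMS per component over a 15 µV pink background (per-band
SNR near 1, total amplitude in the realistic 20-25 µV range); a theta
amplitude gain of 12 µV vs 8 µV (ratio 1.5) between classes. MMSE scores
are integers drawn from a mild-to-moderate range (pre-treatment 10-28),
with responders gaining 1-3 points — a quarter of them held constant to
exercise the tie rule — and non-responders losing 1-3. Per-subject RNG
seeds derive deterministically from the master seed, so cohorts are
reproducible subject by subject.

What the generator does **not** emulate: realistic scalp topographies from
a forward model, eye-blink and EMG artifact morphology, nonstationarity,
or inter-channel differences in spectral shape. Passing the positive and
null controls therefore shows that the pipeline recovers (and does not
hallucinate) a band-power class difference under realistic dimensions and
noise — not that real rTMS response is predictable from theta power.

## Degenerate inputs and edge rules

Empty feature selections (no feature passes the stepwise entry threshold)
return a warning status and a majority-class predictor rather than an
error. Folds whose remaining subjects cannot form the requested balanced
sets are skipped with a logged reason. All-epoch rejection, single-class
training sets, out-of-Nyquist bands and unknown band names raise immediate
errors naming the offending quantity. Amplitude rejection differs by
subject, so the cohort feature matrix truncates every subject to the
cohort-minimum window count to keep columns aligned.

## Problem sizes used in the shipped runs

The test suite validates the full study conditions (14 subjects,
30 channels, 4-minute recordings) over a fixed suite of ten generator
seeds for the positive and null controls; unit tests use smaller cohorts
(2-6 channels, 20-120 s) where the property under test does not depend on
scale. The acceptance script re-runs the positive-control, null-control
and direct-classification analyses on three cohorts derived from its
command-line seed. These sizes are the package's own choice of a
convincing-but-compact demonstration; nothing in the methods depends on
them.

## Known limitations

The engine treats the two recordings per subject (before and after the
treatment course) as separate cohorts run through the identical pipeline;
no combined-recording mode exists. The MMSE labeling rule is a coarse
binary endpoint. The interval-shrinking search is a local refinement — on
multimodal validation landscapes it inherits the usual risk of stopping at
a local maximum, which the grid-search mode exists to check. And the
synthetic validation bounds what the pipeline can claim about real data:
it demonstrates correct machinery, not clinical validity.
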