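---
title: "Modelling ERP correlates of traffic-sign recognition errors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ERP correlates of traffic-sign recognition errors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erpsign)
```

## The scientific setting

Elderly drivers misread traffic signs more often than young drivers, and
the misreading leaves a trace in the EEG. In the Go/Nogo paradigm this
package models, a subject watches pairs of traffic-sign shapes (triangle,
circle, rectangle) — one on a head-up display, one on a front monitor —
and clicks the left mouse button when the pair differs (75% of trials)
and the right button when it matches (25%), within a 1.8 s deadline.
Each of the three shapes is tested in a block of 20 trials. A trial is
*incorrect* when the wrong button is pressed or no response arrives in
time.

Stimulus-locked EEG epochs (−1 to +2 s around stimulus onset) are
averaged per person and condition, and four event-related potential
(ERP) components are read off the averaged trace:

* **N200** — negative deflection, 150–350 ms; stimulus
  identification/mismatch detection,
* **P300** — positive deflection, 250–500 ms; its latency indexes
  attention and cognitive speed and grows with age,
* **N400** — negative deflection, 250–600 ms; memory search,
* **P600** — positive deflection, 500–800 ms; late re-analysis.

The central empirical observations the pipeline reproduces on synthetic
data are: (i) incorrect answers delay the P300 by roughly 20–30 ms in
both age groups, (ii) incorrect-trial traces fluctuate more than
correct-trial traces, and (iii) the two answer classes can be separated
by classifiers trained on the averaged traces.

## The synthetic generator

No recordings are deposited with the study, so `erpsign` ships a
generator (`synthetic_config()`, `make_erp_epoch()`, `make_trial_log()`,
`make_dataset()`) whose defaults *are* the study conditions, and every
downstream stage is validated against it.

Each epoch is a sum of four Gaussian bumps plus band-limited noise:

$$x(t) \;=\; \sum_{c} A_c \exp\!\left(-\frac{(t-\ell_c)^2}{2 w_c^2}\right)
\;+\; \varepsilon(t), \qquad
\varepsilon \sim \text{bandpass}_{4-30\,\text{Hz}}\big(\mathcal{N}(0,
\sigma^2)\big)$$

* **Latencies** $\ell_c$ default to the published group-average
  correct-answer values (elderly 236/398/509/640 ms, youth
  220/396/507/626 ms). Incorrect-condition epochs shift each component
  by the published gap times (elderly +12/+29/+14/−12 ms, youth
  +32/+31/−7/+20 ms).
* **Waveform.** The source study never states a waveform model; a
  Gaussian bump is the simplest smooth, unimodal, polarity-correct
  choice, and its width parameter maps directly onto what the detector
  must resolve.
* **Amplitudes** (−5/+8/−5/+6 µV) and **widths** (σ = 15/20/18/20 ms)
  are this package's choices of realistic smoothed-ERP morphology:
  amplitudes in the single-digit-microvolt range with the P300
  dominant, and deflection widths of ~35–50 ms FWHM as seen in
  filtered single-subject averages. They were fixed once, after a
  design-time study of how peak overlap biases detection (widths much
  above ~25 ms let neighbouring bumps and filter side lobes shift each
  other's extrema by more than one sample), and are not tuned
  thereafter.
* **Noise** is white Gaussian band-passed to 4–30 Hz — the analysis
  band — and rescaled so its post-filter standard deviation equals
  `noise_sd_uV` (default 4 µV per single trial, i.e. half the P300
  amplitude; a 20-trial average then carries ≈0.9 µV residual noise,
  typical of clean averaged ERPs). Incorrect-condition epochs multiply
  the noise by `fluctuation_gain_incorrect` (default 2), encoding the
  observation that error-trial traces fluctuate more. Because incorrect
  trials are also rarer (~20%), their per-person averages are noisier
  twice over, exactly as in real data.
* **Behavior.** Error probabilities default to the published per-shape
  error percentages (elderly 24.1/18.5/19.8%, youth 12.4/16.2/15.3%).
  A configurable share of errors (default 0.2) are timeouts
  (`response = "none"`); the split between wrong clicks and timeouts is
  not published, and 0.2 is a plausibility choice. Response times are
  truncated normal (mean 900 ms elderly / 700 ms youth, sd 150 ms,
  clipped to the 1.8 s deadline) — metadata only; no analysis consumes
  them. The stimulus duration is recorded as 200 ms metadata; the study
  text says "0.2 ms" in one place and "0.2 s" in another, and the
  simulator does not take sides beyond storing the value.

What the generator does **not** emulate: multi-channel topography (a
single region-of-interest trace is generated directly; `roi_average()`
handles multichannel input when provided), ocular/muscle artifacts,
drifts below 4 Hz, trial-to-trial latency jitter within a condition, and
any dependence of the ERP on the specific shape. Passing tests therefore
show that the *analysis chain* is correct under the stated statistical
structure, not that it would perform identically on raw laboratory
recordings.

## Preprocessing variants

`apply_variant()` implements the four processing choices compared
throughout:

1. `original_avg` — the averaged trace as is,
2. `smoothed` — 20 ms centered moving average,
3. `zero_phase` — 4–30 Hz Butterworth band-pass (order 4) run forward
   and backward (`signal::filtfilt`), cancelling phase shift,
4. `zero_phase_smoothed` — filter, then smooth.

Numerical choices: the smoothing window length is rounded to samples
and forced odd so the window is centered; at the edges the window
shrinks instead of padding, so no data is invented and length is
preserved. The kernel is a plain moving average — the source describes
only a "20 ms time window". The filter family is Butterworth because it
is the standard monotone-passband choice; "zero-phase" is the only
property the source states. All variants are linear, which the test
suite exploits (checked to ~1e-5 relative tolerance; the
forward-backward low-band filter loses a few digits to cancellation).

## Component detection and the fixed-gap-time fallback

`detect_components()` chains four window-constrained extremum searches:

* N200: most negative interior local minimum in 150–350 ms (window
  minimum if no interior extremum exists),
* P300: largest interior local maximum in 250–500 ms occurring after
  the N200; if none qualifies, the search moves to the **fixed gap
  time** window `n200 + 250 ± 100` ms, and as a last resort the global
  maximum of that window is taken (`via_fgt = TRUE`),
* N400: most negative local minimum between the P300 and 600 ms,
* P600: largest local maximum between the N400 and 800 ms.

Design decisions where the source is pictorial or silent: an
"appropriate" peak is formalised as an interior local extremum with a
configurable prominence (default 0 — any interior extremum); the FGT
window half-width is 100 ms (a window is shown but not dimensioned);
ties between equal extrema break toward the earlier time, since latency
is the quantity of interest; and the N400/P600 windows are constrained
to start after the preceding component so detected latencies are always
ordered, which the nominal (overlapping) ranges alone would not
guarantee.

On noiseless defaults the detector recovers every configured latency
exactly. Under the default noise (half the bump amplitude per trial,
20-trial averages, `zero_phase_smoothed`), the recovery RMSE is about
4 ms — but the error distribution is heavy-tailed: in roughly 1 in 400
averaged traces the N200 search locks onto the band-pass undershoot of
the neighbouring P300 (~100 ms error), which can dominate a
squared-error summary. This is an inherent hazard of
window-plus-extremum detection on filtered data and is precisely the
failure mode the fixed-gap-time fallback exists to absorb for the P300.

For classification, a 1 s segment is cut starting at the detected N200
(`extract_feature_window()`) and linearly resampled to 70 points
(`resample_features()`), matching the classifier input width.

## Summary statistics

All group-level tables use the arithmetic mean and the **population**
standard deviation (divisor *n*; `mean_and_popsd()`). Error rates are
reported under two conventions, because the published per-shape
percentages are not internally consistent with either alone: the
default `error_rate` is the ratio of mean counts
(`mean_incorrect / (mean_correct + mean_incorrect)`, the convention
that reproduces the published group-average row), and
`error_rate_subject` is the mean of per-subject ratios. Gap times are
rounded differences of mean latencies (`latency_gaps()`); feeding the
published group-average rows reproduces all eight published gap values
exactly. The published per-component SD rows are *not* recoverable from
the published per-shape values under any divisor convention (they
evidently summarise unpublished per-subject data); the acceptance test
records this honestly as a failed reproduction rather than loosening
the comparison.

## Classifiers

**Unsupervised.** Amplitude samples of the 1 s windows of all
correct-answer traces are pooled and clustered into a 10-component
univariate Gaussian mixture by EM (`fit_gmm_em()`): deterministic
quantile-spread initial means, equal weights, pooled variance;
convergence at relative log-likelihood change below 1e-6 (cap 500
iterations); variances floored at 1e-6 of the pooled variance to guard
degeneracy, with a flag when the floor binds. The log-likelihood is
asserted non-decreasing at every iteration. Scoring
(`loglik_difference()`) evaluates correct and incorrect samples under
the correct-answer model and reports `|ll_correct| − |ll_incorrect|`;
well-separated classes give strongly negative values. The observation
model is univariate over pooled samples — the source does not state the
dimensionality, and pooling is consistent with the large magnitudes it
reports; per-subject averaging of scores is the default granularity.

**Supervised.** `train_mlp()` is an explicit 70-20-10-1 network — ReLU
hidden layers, logistic output, binary cross-entropy, full-batch Adam
(learning rate 1e-3, standard moment defaults), 500 epochs,
deterministic given the seed. The backward pass is hand-written so
analytic gradients can be checked against central finite differences
(the suite requires 1e-5 relative agreement). A probability of exactly
0.5 maps to class 1, a fixed convention. `kfold_cv()` shuffles within
class (seeded) and deals samples round-robin into 4 folds, so every
fold holds both classes; fold accuracies are aggregated as mean and
population SD, matching the published aggregation.

The published per-fold accuracies and log-likelihood magnitudes derive
from the undeposited recordings and are **not** reproduction targets;
what the suite asserts instead is the direction of the effect: with the
default incorrect-condition shift (+29 ms P300) and fluctuation gain
(2), 4-fold CV on a simulated 10-subject cohort (≈60 subject × shape ×
condition traces) averages well above 0.6 accuracy across 10 cohorts,
and the GMM difference grows more negative as shift and fluctuation
grow.

## Problem sizes and reproducibility

The test suite and the acceptance script simulate 10-subject cohorts
(600 trials and epochs per cohort), 100-repetition recovery studies,
and 10-cohort cross-validation averages; these sizes keep every
Monte-Carlo estimate's standard error well inside the asserted margins
while remaining comfortable on a single CPU. Every stochastic function
takes an explicit seed, generation is deterministic given
`(config, seed)`, and serialized bundles embed the seed and a
configuration digest so a report can be traced to its inputs. Bundles
are written as JSON with floating-point arrays encoded as 17-digit
decimal strings, which round-trips doubles bit-exactly.

## Known limitations

* The Gaussian-bump ERP model has no trial-level latency jitter, so
  averaging never smears components; real averaged ERPs are broader
  than their single-trial constituents.
* Detection quality degrades sharply once component spacing approaches
  the bump widths; the defaults keep components resolvable by design.
* The GMM observation model discards temporal ordering entirely (pooled
  amplitude samples); it separates classes through amplitude
  distribution and variance, not through latency as such.
* With ~20% error rates, per-person incorrect averages pool only ~4
  trials; their component latencies are accordingly noisy, and
  group-level gap times are best read from grand-average traces, as the
  test suite does.
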