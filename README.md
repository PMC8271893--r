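# erpsign

Event-related potential (ERP) analysis of traffic-sign recognition
errors in elderly vs. young drivers, as a fully simulated and tested
pipeline.

## The problem

In a Go/Nogo traffic-sign task, a driver compares a sign shown on a
head-up display with one shown ahead (75% "different", 25% "same"; 20
trials per shape for triangles, circles and rectangles) and must click
the correct mouse button within 1.8 s. Elderly drivers err more often,
and errors leave a signature in the stimulus-locked EEG: the main ERP
components — N200 (negative, 150–350 ms), P300 (positive, 250–500 ms),
N400 (negative, 250–600 ms), P600 (positive, 500–800 ms) — arrive
late on incorrect trials (P300 by ~20–30 ms), and error-trial traces
fluctuate more.

`erpsign` is for researchers who want a reproducible, data-free
implementation of that analysis chain: a synthetic generator whose
defaults encode the study conditions, the four preprocessing variants,
an automated component-latency detector, the summary arithmetic, and
both correctness classifiers.

## What it computes

* **Synthetic data** (`make_dataset()`): per subject/shape/trial, a
  behavioral record and an epoch
  $x(t) = \sum_c A_c e^{-(t-\ell_c)^2/2w_c^2} + \varepsilon(t)$
  with 4–30 Hz band-limited noise; incorrect trials shift each
  component latency by the observed gap times and double the noise.
* **Preprocessing** (`apply_variant()`): averaged signal, 20 ms
  moving-average smoothing, 4–30 Hz zero-phase Butterworth band-pass
  (`signal::filtfilt`), or filter-then-smooth.
* **Detection** (`detect_components()`): window-constrained extremum
  search for N200/P300/N400/P600, with a fixed-gap-time (FGT) fallback
  for the P300: if no suitable peak lies in 250–500 ms, search
  `n200 + 250 ± 100` ms.
* **Summaries** (`summarize_behavior()`, `summarize_latencies()`,
  `latency_gaps()`): per-group/shape correct/incorrect counts, error
  rates, component latency means with population SDs, and
  incorrect-minus-correct gap times.
* **Classifiers**: a 10-component univariate Gaussian mixture fitted by
  EM to correct-answer amplitudes and scored by
  `|ll_correct| − |ll_incorrect|` (`fit_gmm_em()`,
  `loglik_difference()`), and a 70-20-10-1 ReLU/logistic MLP trained
  with Adam on binary cross-entropy, evaluated by stratified 4-fold
  cross-validation (`train_mlp()`, `kfold_cv()`).

## Worked example

```r
library(erpsign)
report <- run_pipeline(pipeline_config(n_subjects = 10, seed = 1))
print(report)
```

```
<erpsign_report> seed 1, config d664fe01

Behavior (per group/shape):
    group     shape n_subjects mean_correct sd_correct mean_incorrect
1 elderly  triangle         10         14.5       1.57            5.5
2 elderly    circle         10         16.6       1.36            3.4
3 elderly rectangle         10         16.1       1.87            3.9
4   youth  triangle         10         17.4       1.69            2.6
5   youth    circle         10         16.8       1.78            3.2
6   youth rectangle         10         17.6       1.56            2.4
  sd_incorrect error_rate error_rate_subject
1         1.57      0.275              0.275
2         1.36      0.170              0.170
3         1.87      0.195              0.195
4         1.69      0.130              0.130
5         1.78      0.160              0.160
6         1.56      0.120              0.120

Latency gap times (incorrect - correct, ms):
    group component gap_ms
1 elderly      N200    -18
2 elderly      P300     20
3 elderly      N400     11
4 elderly      P600      4
5   youth      N200      3
6   youth      P300     14
7   youth      N400     13
8   youth      P600     23

GMM log-likelihood differences (|correct| - |incorrect|):
    group n_subjects difference_avg difference_sd
1 elderly         10         -404.0         153.7
2   youth         10         -852.5         299.1

4-fold cross-validation:
    group mean  popsd
1 elderly 0.80 0.1224
5   youth 0.79 0.0914
```

Reading the output: the simulated elderly cohort errs more than the
young one (overall ~21% vs ~14%, tracking the configured per-shape
error rates); the P300 gap on per-person averages is positive for both
groups but noisy, because incorrect-trial averages pool only ~4 noisy
trials each — grand-average traces recover the configured +29 ms
elderly shift much more precisely (see the vignette). The strongly
negative GMM differences mean incorrect traces are far less likely
under the correct-answer mixture model than correct traces are, and
the MLP separates the two classes at ~0.8 cross-validated accuracy
under the default shift and fluctuation settings.

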