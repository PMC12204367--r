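---
title: "Models and methods behind abrtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind abrtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`abrtools` automates two measurements from auditory brainstem response
(ABR) recordings: wave 1 latency/amplitude, and the per-frequency hearing
threshold. This vignette explains the models, the choices behind them, and
what the synthetic benchmarks do and do not demonstrate.

## The canonical grid

All analysis happens on a fixed grid of 244 samples spanning 10 ms
post-stimulus (`abr_grid()`), with sample *i* at time *i*·dt,
dt = 10/244 ms. This convention is load-bearing: the three refinement
constants — the 0.4098 ms pre-window, the 0.6557 ms minimum peak
separation, and the 0.2869 ms minimum trough separation — are exactly 10,
16 and 7 samples on it. Recordings at other native rates are truncated to
10 ms and resampled: piecewise-linear interpolation when downsampling
(local averaging behavior, no overshoot), natural cubic splines when
upsampling (smooth interpolant; the natural boundary condition — zero
second derivative, linear extrapolation beyond the last knot — is the
standard default and both branches reproduce degree-≤1 polynomials
exactly). Fewer than four native samples cannot support the spline and is
an error.

## Scaling conventions

Two distinct scalings are deliberate, not redundant:

* **Per waveform** (`scale_waveform()`), used for peak *localization*: each
  trace is z-scored over its own timepoints and min–max scaled to [0, 1].
  Location of extrema is invariant to this increasing affine map, and it
  removes amplitude information the latency regressor should not rely on.
* **Per stack** (`scale_stack()`), used for threshold *classification*: one
  pooled affine map over every sample of every member waveform. Relative
  amplitudes across levels — the very signal that distinguishes supra- from
  sub-threshold traces — are preserved.

A zero-variance trace maps to all 0.5 with a warning rather than erroring,
so one flat channel cannot abort a batch. The phrasing "z-scores for each
timepoint" is ambiguous between scaling across time within a trace and
across traces within a timepoint; we use within-trace (and pooled within
stack) because each quoted scaling is described as applied "over the
waveform" / "over the entire stack", and note that a per-timepoint variant
would destroy the cross-level amplitude ordering the classifier needs.

## Two-step peak detection

A 1-D convolutional network (two blocks of convolution → batch-norm →
ReLU → max-pool → dropout, then a hidden dense layer and a linear unit)
regresses the wave 1 peak index from the scaled 244-sample trace. Training
minimizes (optionally per-source weighted) squared error; labels are
divided by 243 so the regression target lives in [0, 1], and predictions
are unscaled and clamped back into [0, 243]. A continuous regression
output was chosen over 244-way classification because the peak position is
an ordinal quantity and the index is then refined anyway.

The refinement (`refine_peaks()`) is deterministic: Gaussian-smooth the
trace (σ = 1 sample, kernel truncated at 4σ and renormalized,
edge-inclusive reflect padding), scan for local maxima by neighbor
comparison starting 10 samples before the rounded prediction, apply the
16-sample minimum separation, take the first five survivors as waves 1–5,
and match trough *k* to the first (7-sample-separated) minimum after peak
*k* and before peak *k*+1. Two conventions matter:

* **Plateaus** count once, at their leftmost sample — a deterministic
  tie-break consistent with neighbor-comparison scanning.
* **Separation conflicts** resolve by *height*: when two candidate maxima
  are closer than the minimum separation, the taller survives (leftmost on
  exact ties). This mirrors the distance rule of the standard peak-picking
  routine in widespread use, and it is what makes the scan robust near the
  scan start: a small smoothed-noise bump a few samples before the true
  wave 1 peak is suppressed by the much taller true peak, instead of being
  accepted just because it is encountered first.

Voltages are always read from the unsmoothed trace at the found indices,
so amplitudes are never biased by the smoothing bandwidth. If fewer than
five maxima exist before 10 ms, later waves are reported absent; the
separation rule is never relaxed. A trace with no usable maximum yields an
all-absent peak set with a count of zero rather than an exception. The
approach assumes latencies in the normal physiologic range; severely
abnormal latencies can defeat the windowed scan and no mitigation is
attempted.

### Network hyperparameters

Channels 16→32, kernels 9/5, pool width 2, one hidden dense layer of 64
units, Adam with step decay (learning rate halved every 30 epochs), batch
64. Dropout defaults to 0.05 and the base learning rate to
2×10⁻³ for the regressor: at the few-thousand-waveform training sizes this
package targets, heavier dropout (e.g. 0.25) leaves the localization net
visibly underfit (validation index error ~4× worse), while the small net
plus early stopping already controls overfitting. Both are config-exposed
(`peak_regressor_config()`), as are all architecture constants. The
network engine itself (convolution as shifted matrix products, standard
batch-norm statistics with running means for inference, inverted dropout,
Adam) is part of the package and is verified against finite-difference
gradients in the test suite.

## Threshold estimation

A binary classifier scores each preprocessed waveform; "above threshold"
is the positive class. The stack threshold is the quietest tested level
called positive (`rule = "literal"`, the definitional reading). Because a
single false positive deep below threshold would then set the threshold,
`rule = "contiguous"` — the quietest level of the unbroken positive run
from the loudest level — is offered as a robust variant; both rules return
`Inf` ("no response", written `NR` in CSV exports) for all-negative stacks
and are monotone: turning any call positive can never raise the estimate.
Thresholds are always members of the tested level set, never interpolated.

Three families: the CNN (three conv blocks, two dense layers, sigmoid
head) consumes stack-scaled traces; boosted trees and ridge-regularized
logistic regression consume stack-scaled, time-warp-aligned traces —
alignment removes the level-dependent latency shift those flat models
cannot express, while the CNN's pooling gives it some translation
tolerance of its own. The 244 scaled voltages are the only features;
stimulus level is deliberately excluded to avoid leaking the label through
the level ordering. The operating point on the score defaults to 0.5 and
is configurable, since no single point suits every cost trade-off.

## Time warping

`align_stack()` aligns each member of a stack to a reference (default: the
loudest level) by landmark-guided piecewise-linear warping: detected peaks
(smoothed local maxima, separation rule as above, up to five) are matched
to the nearest reference landmark within 0.6 ms, non-monotone matches are
dropped, and the warp is the monotone piecewise-linear map through the
matched pairs with fixed endpoints γ(0) = 0, γ(10 ms) = 10 ms. Warped
traces are re-evaluated by linear interpolation, so landmark samples are
preserved exactly and other samples up to interpolation error. A waveform
is considered landmark-bearing only if (max − median)/MAD of its smoothed
trace exceeds 4.5: pure recording noise scores about 2.6 ± 0.4 on this
statistic regardless of its sd, clear responses 5–8, and ambiguous traces
safely receive the identity warp — as do all sub-threshold, noise-only
members. Amplitude extrema of response-dominated traces change by well
under 2 % after warping; the global extremum of a noise-only trace is a
single-sample spike and can lose more than that to off-sample
re-evaluation, which is why the amplitude-preservation guarantee is stated
for responses, not for noise.

## The synthetic generator

`generate_dataset()` emulates exactly the structure the models must learn:

* five biphasic waves (positive Gaussian lobe, negative lobe 0.3 ms later
  at 0.7× depth; widths 0.16/0.14 ms) at base latencies 1.5, 2.5, 3.4,
  4.4, 5.3 ms — roughly the murine configuration, with ~1 ms inter-wave
  spacing comfortably above the 0.6557 ms separation constant;
* latencies shorten by 0.01 ms/dB as level rises, amplitudes grow
  sigmoidally (rate 0.1/dB) above a per-stack threshold drawn uniformly
  from the tested levels between 25 and 70 dB;
* below threshold, the trace is Gaussian recording noise only
  (sd 0.15 μV by default, against ~0.6–1.8 μV wave 1 amplitudes);
* per-subject random effects (latency ±10 %, amplitude ±20 %, truncated at
  ±2 sd so wave spacing stays refinable) make subject-level splits
  meaningful;
* optionally, named sources with different native sampling rates (e.g.
  244 vs 488 points per 10 ms) exercise resampling and per-source loss
  weighting.

Ground-truth peak/trough locations are defined as the extrema of the
σ = 1-smoothed noise-free composite (amplitudes are read from the raw
composite at those indices). The smoothed extremum is the quantity the
two-step detector estimates; on asymmetric biphasic sums it can sit one
sample (0.041 ms) away from the raw argmax, an immaterial offset that
would otherwise contaminate exactness checks.

What the generator does **not** emulate — real electrophysiological
artifacts (movement, mains interference), non-Gaussian noise, gradual
amplitude decay toward threshold (the supra/sub transition here is sharp),
frequency-dependent morphology changes, or pathological waveforms. Passing
synthetic benchmarks therefore demonstrates that the algorithms and
training machinery recover what they are designed to recover under
realistic geometry and noise; it does not certify performance on abnormal
or out-of-distribution animal data.

## Training and evaluation machinery

* **Splits** are by subject, never by waveform, 80/20 per source with 20 %
  of the training pool for validation; counts round to the nearest subject
  with a minimum of one per partition, after a seeded shuffle.
* **Source balancing**: weight *N*/(*S*·n_source) per sample, so each
  source's weights sum to *N*/*S* regardless of its size.
* **Augmentation** doubles the training matrix with one copy per original
  (kind drawn uniformly among noise injection sd 0.02 of the scaled range,
  elastic control-point jitter ±2 samples via cubic-spline re-evaluation,
  and time shift ±3 samples, edge-replicated). Magnitudes are
  config-exposed; they are small on purpose — augmentation should perturb,
  not relabel.
* **Early stopping**: training halts once the validation loss has not
  strictly improved for 25 consecutive epochs and the best epoch's weights
  are restored. The rule is implemented once (`early_stopping_trace()`)
  and used by the trainer, so it can be verified on scripted loss
  sequences.
* **Metrics**: trapezoidal AUCROC (provably equal to tie-aware pairwise
  concordance), step-integrated AUCPR, accuracy/TPR/FPR at the operating
  point, RMSE/MAE with seeded percentile bootstrap CIs (2,000 resamples —
  the unpaired percentile bootstrap was chosen absent a stated pairing),
  within-k-dB agreement (a pair of no-response calls counts as a hit, a
  one-sided no-response as a miss), and pooled two-sample z-tests on
  proportions with optional Bonferroni adjustment.

## Problem sizes and determinism

The shipped benchmarks train the peak regressor on ~2,100 supra-threshold
waveforms from 85 simulated subjects at four frequencies and score ~650
held-out waveforms with true amplitude ≥ 3× the noise sd (near-threshold,
noise-dominated traces are the known dominant error source and are
reported separately); the threshold CNN trains on ~45 stacks (22 subjects,
three frequencies, 5 dB steps) and is scored on a fresh 51-stack cohort.
These sizes were chosen as the smallest at which both pipelines reach
stable recovery (latency MAE well under 0.1 ms; ≥95 % of thresholds within
10 dB) on a single CPU in minutes. Every stochastic step — simulation,
splits, initialization, shuffling, dropout, augmentation, bootstrap — is
seeded, and inference is deterministic (batch-norm running statistics,
dropout disabled), so identical inputs give identical outputs.

## Known limitations

* Waves 2–5 are located but not validated against any human-labeled truth.
* The refinement constants (10/16/7 samples) assume near-normal latencies;
  no fallback exists for grossly abnormal morphology.
* The score cut-off (0.5) and the threshold rule interact: on stacks with
  isolated false positives the literal rule is biased low; use
  `contiguous` when that risk matters.
* The CNN engine is plain R matrix code: adequate for the package's
  problem sizes (minutes per model on one CPU), not for datasets orders of
  magnitude larger.
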