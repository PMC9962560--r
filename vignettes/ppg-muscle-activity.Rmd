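---
title: "Inferring upper-arm muscle activity from wrist PPG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring upper-arm muscle activity from wrist PPG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppgmuscle)
library(dplyr)
```

## The measurement principle

Surface electromyography (sEMG) is the standard way to quantify muscle
activation, but electrodes, gel and tape make it impractical for everyday
wear. `ppgmuscle` implements an indirect route that needs only a wrist
photoplethysmography (PPG) sensor — the pulse-wave sensor in any smartwatch —
plus an elastic band on the upper arm. When the upper-arm muscles contract
beneath the band, they compress the brachial artery, and the pulse wave
measured distally at the wrist weakens. Muscle activity therefore leaves a
readable signature in the wrist pulse:

* **Classification.** Four held arm states are distinguished — (1) `normal`,
  arm hanging down; (2) `bend`, arm bent; (3) `strength`, bent with strain;
  (4) `dumbbell`, bent holding a 5 kg weight. States (3) and (4) produce
  nearly identical pulse signatures and are merged into one `strain` class
  (3') for the headline 3-class task.
* **Regression.** The sEMG root-mean-square (RMS) over a 2-s span — the
  standard scalar summary of activation intensity — is predicted from the
  raw 2-s PPG window ending at the same instant.

PPG is sampled at 100 Hz and sEMG at 1000 Hz, so a 2-s span is 200 PPG
samples and 2000 EMG samples; both streams share a wall-clock time axis, and
sample indices are recovered by rounding `t * fs`.

## Feature model for classification

A sliding window of `N = 200` samples (2 s) with 50% overlap is cut from
each 10-s segment, left-aligned at the first sample; a trailing partial
window is discarded. One 10-s segment yields exactly 9 windows. Each window
`p(t)` is transformed with a raw, untapered discrete Fourier transform

$$X(k) = \sum_{t} p(t)\, e^{-j 2 \pi k t / N},$$

and the one-sided power spectrum $P(k) = |X(k)|^2$, $k = 1 \dots N/2$, is
the 100-dimensional feature vector. Design choices worth noting:

* **No taper or detrend.** The DFT is applied to the raw window; the method
  relies on relative spectral structure, not leakage-free estimates.
* **DC dropped by default.** Bin 0 mostly encodes sensor offset; dropping it
  makes features invariant to constant baselines (`drop_dc = FALSE` keeps
  it).
* **Unnormalized power.** No `1/N` factor anywhere, so absolute values are
  arbitrary-unit; only relative structure matters to the classifier.

A random forest (`ranger`, 100 trees, default split criteria, fixed seed,
single-threaded for reproducibility) maps $P(k)$ to the state label. The
forest's prediction seed is pinned to the training seed because vote ties
are otherwise broken randomly.

## The RMS regressor

The regression target is the trailing RMS
$r(T) = \sqrt{\tfrac{1}{10N}\sum s(t)^2}$ over the 2000 EMG samples ending
at `T`. (The canonical index range for this sum is ambiguous by one sample;
we use exactly `10N` trailing samples, consistent with the stated 2-s
span.) Each PPG window ending at `T` is annotated with `r(T)`; on the
default grid the first window ends at `T = 2` s, so no window underflows the
recording.

The regressor is a small 1-D convolutional network implemented natively in
this package (forward and backward passes, im2col convolutions, Adam):

```
[conv(kernel 3, 'same') -> ReLU -> maxpool(2)] x 2 (16, 32 filters)
-> flatten -> dense(128) -> ReLU -> dropout(0.5) -> linear(1)
```

Kernel size 3, pool size 2, 128 hidden units, dropout 0.5, batch size 64,
Adam, and an L1 (mean absolute error) loss are fixed architecture
constants; the block count (2) and filter counts (16, 32) are this
package's choice — the smallest standard shape for a twice-pooled
200-sample input. Further numerical choices:

* **Input standardization**: each window is shifted to zero mean, removing
  the PPG DC offset.
* **Target scaling**: targets are divided by their training-set mean and the
  scale is undone at inference. sEMG RMS magnitudes span roughly 60--3500
  across subjects; without scaling, the L1 loss scale (and hence effective
  learning rate) would vary wildly.
* **Optimization**: learning rate `1e-3`, at most 100 epochs, early stopping
  on a 10% validation split with patience 10 and best-weights restore. An
  optional per-epoch learning-rate decay (`lr_decay`) is available: L1
  gradients keep constant magnitude near the optimum, so Adam orbits it at
  a radius proportional to the learning rate, and annealing is needed when
  tight pointwise convergence matters.
* **Output clamp**: predictions are clamped at 0, since an RMS is
  non-negative by definition.
* **Dropout** is active only during training; inference is deterministic.

The backward pass is verified against finite differences in the test suite,
probing one coordinate of every parameter tensor.

## Evaluation protocols and metrics

* **Per-class precision, recall, F-value.** Conventional definitions
  (precision `TP/(TP+FP)`, recall `TP/(TP+FN)`); the F-value is their
  harmonic mean, `2TP/(2TP+FP+FN)`. Because the harmonic mean is symmetric,
  the F-value is unchanged if the two component ratios swap names.
* **Error rate** for regression: `mean(|y - r|) / mean(r)`, computed per
  state. Both numerator and denominator are means over windows, which makes
  the metric scale-free; a predictor stuck at zero scores exactly 100%.
* **User-dependent protocol**: per subject, k-fold cross-validation whose
  folds partition *segments*, stratified by state — never windows.
  Overlapping windows from one segment would otherwise leak between
  training and test. With 30 segments per state and `k = 10`, each fold is
  the canonical 27-train / 3-test split; regression evaluates a configurable
  subset of folds because CNN training dominates runtime.
* **User-independent protocol**: leave one subject out, train on all
  windows of the rest. Because the classifier keys on absolute spectral
  power, transfer collapses when subjects' pulse amplitudes occupy disjoint
  ranges — the characteristic failure mode of this sensing principle.

Whether the original folds were stratified by state is not documented
anywhere; we stratify, which keeps class balance exact in every fold.

## The synthetic study generator

No recordings for this measurement setup are public (they are biometric
data), so the package ships a generator that emulates the statistical
structure the method assumes, and every test and demo runs on it. One
virtual subject is a `subject_profile()`; a `generate_study()` reproduces
the acquisition protocol: per subject and state, 30 repetitions held for
10 s (rest periods between repetitions are not generated — only held states
enter analysis). Each segment's seed derives injectively from the study
seed, so studies are bit-reproducible.

**PPG model.** Beats repeat with the subject's period (defaults drawn from
0.7--1.1 s); each beat is a Gaussian systolic upstroke (peak at 18% of the
period) followed by an exponential diastolic decay. The decay rate is
state-dependent: 8 s⁻¹ for the arm-down state (pulse falls off
fast), 4.5 for the bent arm (gentle), 1.5 for the strained states, whose
pulse is low and flattened with the peak hard to pick out. Pulse amplitude
is `base_amp * attenuation[state]`, with default attenuations
1 : 0.759 : 0.701 : 0.677. These are the square roots of the power ratios
1 : 0.58 : 0.49 : 0.46 observed between state-wise power-spectrum maxima in
real tourniquet-compressed recordings; applying the square root to
amplitude reproduces those *power* ratios in the simulated spectra (the
absolute units of the reference values are unknown, so only ratios are
matched). Gaussian sensor noise (sd 0.03) is added.

**sEMG model.** Zero-mean Gaussian noise band-passed to 20--450 Hz (the
conventional surface-EMG bandwidth; zero-phase 4th-order Butterworth), then
rescaled so the full-segment RMS equals the state's `emg_sigma` exactly.
Defaults 422 / 848 / 1261 / 2351 are a realistic mid-range magnitude spread
for the four states in microvolts.

**Variability.** Two jitter sources make the cohort realistic rather than
trivially separable:

* per-beat amplitude jitter (log-normal, sd 0.1) — pulse amplitude varies
  beat to beat even at rest;
* per-repetition *force* jitter (log-normal, sd 0.06), shared between the
  two channels of a pair: a repetition held with more force compresses the
  artery harder (PPG amplitude scaled by `exp(-0.06 z)`) and recruits more
  muscle (EMG RMS scaled by `exp(0.048 z)`).

These two sources were calibrated once, during generator design, so that a
default within-subject study reproduces the qualitative recognition
structure seen in real data: the arm-down and bent states partly blur into
each other, while the merged strain class stays the most recognizable; with
the calibrated defaults, within-subject 3-class F-values land near
0.90--0.98 with `strain` highest.

**What the simulator does *not* model** — and therefore what passing tests
do not certify about real data: motion artifacts, sensor misalignment,
baseline wander, heart-rate variability within a segment, dicrotic-notch
morphology, EMG bursts or onset dynamics (the EMG is stationary within a
segment), fatigue drift across repetitions, and any physiological
arterial-compliance mechanism. Results on this cohort demonstrate that the
pipeline recovers structure *of the kind the method assumes*, not field
performance.

## Problem sizes used in the checks

The bundled checks run a one-subject study (30 repetitions per state, 1080
windows) for within-subject classification and regression, and 5-subject
cohorts (600 segments, 100 min of PPG) for the protocol arithmetic and the
transfer experiments; the regression check evaluates one fold of the
10-fold scheme (the 27/3 split). These sizes mirror the reference
acquisition protocol per subject while keeping a full run in the
single-digit minutes on one CPU core.

## A worked example

```{r example, eval = FALSE}
study <- generate_study(default_profiles(1, seed = 1), reps_per_state = 30,
                        seed = 1)

# 3-class recognition, within-subject 10-fold CV
clf_report <- cv_user_dependent(study, k = 10, task = "classify", seed = 1)
tidy(clf_report)

# EMG RMS regression on the 27/3 split
reg_report <- cv_user_dependent(study, k = 10, task = "regress", seed = 1,
                                folds = 1)
tidy(reg_report)
autoplot(reg_report)
```

## Known limitations

* The CNN trains on a single CPU core in plain R; a full 10-fold regression
  evaluation takes tens of minutes. Use `folds =` to evaluate a subset.
* The simulator's force jitter couples the channels log-linearly; real
  force--EMG and force--compression relations are nonlinear and
  subject-specific.
* Cross-subject regression is not evaluated by default: the classification
  transfer experiment already shows the amplitude-keyed representation does
  not transfer, and the same limitation applies a fortiori to regression.
* All defaults describe a resting, stationary subject; none of the
  conclusions extend to dynamic movement.
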