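# ppgmuscle

Infer upper-arm muscle activity from wrist photoplethysmography (PPG).

When an elastic band sits on the upper arm, contracting the arm muscles
compresses the brachial artery, and the pulse wave measured distally at the
wrist weakens. `ppgmuscle` turns that coupling into two estimators that need
nothing but a smartwatch-class PPG sensor at run time:

* **State classification.** A random forest on the one-sided FFT power
  spectrum `P(k) = |X(k)|²` of 2-s PPG windows (100 Hz, `N = 200`, 50%
  overlap) distinguishes three arm states: *normal* (arm down), *bend*
  (arm bent), and *strain* (bent with strain or holding a 5 kg dumbbell —
  two recorded states merged, since their pulse signatures are nearly
  identical).
* **EMG-RMS regression.** A small 1-D CNN
  (`[conv3–ReLU–pool2] × 2 → dense(128) → dropout(0.5) → linear`),
  implemented natively in this package and trained with an L1 loss and
  Adam, maps each raw 2-s PPG window to the surface-EMG root-mean-square
  `r(T) = sqrt(mean(s(t)²))` over the 2000-sample EMG span (1000 Hz) ending
  at the same instant.

Evaluation follows the field's protocols: segment-level stratified k-fold
cross-validation within a subject (never window-level, to prevent overlap
leakage), the 27/3 segment split for regression, and leave-one-subject-out
transfer. Metrics are per-class precision/recall/F-value
(`F = 2TP/(2TP+FP+FN)`) and the per-state relative error rate
`mean(|ŷ − r|)/mean(r)`.

Because recordings for this measurement setup are biometric and not public,
the package ships a synthetic paired PPG/sEMG study generator
(`generate_study()`) that reproduces the statistical structure the method
relies on — state-dependent pulse attenuation and diastolic decay,
band-limited stochastic sEMG with state-dependent RMS, beat- and
repetition-level variability — and every test and example runs on it. See
`vignettes/ppg-muscle-activity.Rmd` for the models, defaults and their
rationale.

## A worked example

```r
library(ppgmuscle)
library(dplyr)

# one virtual subject, 30 repetitions of 10 s per state, both channels
study <- generate_study(default_profiles(1, seed = 1), reps_per_state = 30,
                        seed = 1)

# 3-class recognition, within-subject 10-fold segment-level CV
clf <- cv_user_dependent(filter(study, channel == "ppg"),
                         k = 10, task = "classify", seed = 1)
tidy(clf)
#> # A tibble: 3 × 8
#>   class     tp    fp    fn    tn precision recall f_value
#>   <chr>  <int> <int> <int> <int>     <dbl>  <dbl>   <dbl>
#> 1 bend     249    16    21   794     0.940  0.922   0.931
#> 2 normal   261    10     9   800     0.963  0.967   0.965
#> 3 strain   533    11     7   529     0.980  0.987   0.983

# EMG RMS regression on the 27/3 split (fold 1 of the same 10-fold scheme)
reg <- cv_user_dependent(study, k = 10, task = "regress", seed = 1, folds = 1)
tidy(reg)
#> # A tibble: 4 × 3
#>   state    error_rate n_windows
#>   <fct>         <dbl>     <int>
#> 1 normal        0.106        27
#> 2 bend          0.128        27
#> 3 strength      0.221        27
#> 4 dumbbell      0.316        27
```

Reading: each 10-s segment yields 9 windows, so the classifier sees 1080
windows (270 per state, strain = 2 × 270). F-values near 0.9 with *strain*
the most recognizable class mirror what this sensing principle achieves on
real recordings; the regression error rate of ≈ 19% on average (worst for
the dumbbell state, whose pulse is weakest) matches the ≈ 20% ballpark
reported for real data. Cross-subject transfer is the known failure mode:
with subjects whose pulse amplitudes occupy disjoint ranges,
`eval_user_independent()` F-values collapse (macro-F drops by ≈ 0.5).

`plot_segments()`, `plot_mean_spectra()` and `autoplot()` on any report or
trained regressor give the corresponding figures; `tidy()`/`glance()` work
on classifiers, regressors and evaluation reports. A command-line front end
over the same functions lives at `inst/cli/ppgmuscle.R`
(`simulate`, `featurize`, `train-clf`, `train-reg`, `predict`, `evaluate`,
`run-all`).

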