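---
title: "Personalized glucose excursions from noninvasive wearables: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalized glucose excursions from noninvasive wearables: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
models and their assumptions, the parameters that matter, what the synthetic
cohort generator does and does not emulate, and the numerical and design
choices made where the method left them open.

## The problem

Continuous glucose monitors report interstitial glucose every 5 minutes, but
they are invasive and rarely prescribed outside insulin-dependent diabetes.
For people with prediabetes or high-normal HbA1c, glucose excursions that
matter are often invisible to the clinical 70/180 mg/dL thresholds: a
sugary drink can push one person from 95 to 150 mg/dL — a large deviation
*for them* — without ever crossing 180. The pipeline in this package
therefore (1) defines excursions relative to each person's own moving
baseline, (2) asks whether those excursions can be classified from a wrist
wearable plus a food log, and (3) asks whether the glucose value itself can
be predicted from the same noninvasive inputs.

## Personalized excursion labels

For a reading $g(t)$, let $\mu_{24}(t)$ and $\sigma_{24}(t)$ be the mean and
sample (n−1) standard deviation of readings in $[t-24\mathrm{h},\, t)$, the
reading itself excluded. The label is PersHigh if
$g > \mu_{24}+\sigma_{24}$, PersLow if $g < \mu_{24}-\sigma_{24}$, and
PersNorm otherwise, with boundary values read as "within one standard
deviation" and hence PersNorm. Points with fewer than `min_history_points`
readings in their window (default 144, i.e. 12 h of 5-min readings) are left
unlabeled and excluded downstream; in practice this drops roughly the first
half day of wear. How the very first day should be handled is genuinely
underdetermined — the convention here keeps early labels from resting on a
baseline estimated from a handful of points, and the threshold is a config
knob.

The labeling is invariant to adding a constant to the whole series and to
positive rescaling, which the test suite asserts; on an i.i.d. Gaussian
series the PersNorm fraction approaches $\Phi(1)-\Phi(-1) \approx 0.683$,
which the suite verifies at $n = 50{,}000$.

## The 69 features and the historical rule

Every feature for a target at time $t$ uses only data from strictly before
$t$. Concretely, all windows are half-open $[t-w,\, t)$: the per-epoch
sensor summaries attached to the row for $t$ come from the epoch *labeled*
$t-5$ min (covering $[t-300\mathrm{s}, t)$), and the 2/8/24-h rollups cover
the epochs ending at $t$. This single convention keeps every feature
strictly causal, and the suite enforces it adversarially: corrupting any
sensor sample, food entry or later glucose value at times $\ge t$ must leave
the feature row for $t$ bit-identical.

Group by group:

* **Data-driven summaries (28).** Mean, sample sd, min, max, first and
  third quartile (linear interpolation of order statistics), and adjusted
  Fisher–Pearson skewness, for heart rate (bpm), accelerometry vector
  magnitude ($\sqrt{x^2+y^2+z^2}$, device units of 1/64 g), electrodermal
  activity (µS) and skin temperature (°C). A window with fewer than 2
  samples yields missing values; the skewness of a zero-variance window is
  defined as 0 so a flat-but-working sensor does not propagate missingness.
* **Heart-rate variability (8).** From inter-beat intervals falling in the
  epoch, in milliseconds: mean, median, max, min interval; SDNN (sample sd);
  RMSSD (root mean square of successive differences); NN50 (successive
  differences > 50 ms); pNN50 = NN50 divided by the *number of intervals* —
  the stated definition, kept literally even though some HRV software
  divides by the number of differences.
* **Electrodermal peaks (3).** A "unique peak" is a local maximum with
  topographic prominence ≥ 0.3 µS after enforcing a minimum separation of 4
  samples (1 s at 4 Hz); when two candidates are closer, the higher (ties:
  earlier) survives. Prominence is measured against the higher of the two
  minima separating the peak from the nearest taller sample on each side,
  window edges acting as bases. Per-epoch counts are rolled up as the total
  and the per-epoch mean over the previous 2 h, sharing the 2-h window.
* **Activity (5).** An epoch is an activity bout when its mean ACC vector
  magnitude *and* its mean heart rate both exceed the participant's
  expanding averages over all prior epochs (first epoch: never a bout).
  Rollups: bouts in the previous 1 h, mean bouts over the previous 24 h, and
  the mean and max of the per-epoch ACC summaries over the previous 2 h.
* **Circadian (3).** Minutes and hours from local midnight (a per-cohort
  `tz_offset` converts UTC to wall clock; timestamps are stored as UTC epoch
  seconds because a wall-clock convention has to be fixed somewhere), and a
  daily wake time. Wake detection flags each epoch 0 when at least two of
  {ACC mean, ACC sd, HR mean, HR sd} fall below that day's average, smooths
  the 0/1 series with a 3-h trailing mean, and takes the earliest epoch
  whose smoothed first difference exceeds a slope threshold while the
  smoothed values 25 and 75 minutes later remain higher. Because the
  day-average is only known once the day has elapsed, the feature at time
  $t$ carries the wake time of the most recent *fully elapsed* day — the
  only reading consistent with the historical rule. The default slope
  threshold is 0.02 per epoch: a clean step in the indicator passes through
  a 36-epoch trailing mean at slope exactly 1/36 ≈ 0.028, so the threshold
  must sit below that to fire on an unambiguous sleep–wake transition; it is
  exposed as `wake_slope_threshold`.
* **Food (19).** Sums of calories, protein, carbohydrates and sugar over
  2/8/24-h windows; a binary flag for an eating event in the most recent
  historical epoch; eating-event counts over the three windows; and the
  counts divided by the number of 5-min epochs in each window.
* **Demographics and personalization (3).** Sex (0/1), HbA1c (%), and the
  participant id as a numeric model input, letting tree models carve
  person-specific structure.

The full list is `feature_schema()`; it reconstructs the published feature
set from the described procedures and the names used in the importance
ranking, since the original enumeration lives in supplementary material.
The taxonomy mapping each feature to a category, data source and
engineering method ships as `inst/extdata/feature_taxonomy.csv`
(28 data-driven, 38 domain-driven, 3 other).

**Missing cells** are imputed per participant by forward fill; missing
values before a column's first observation take that first observed value.
A whole-table median — the obvious alternative — would read future rows and
break the causality guarantee, so it is not offered as a default.

## Models

**Classification.** Classes are balanced once, before cross-validation, by
undersampling to the minority class. The scheme is repeated stratified
k-fold (10 splits × 3 repeats); within each fold a recursive feature
elimination — fit the estimator, drop the least important feature, repeat —
reduces 69 features to 20 using decision-tree importances (logistic,
perceptron, random-forest and gradient-boosting estimators are available;
the tree is the default), and a decision tree is fit on the survivors. A
70/30 stratified holdout with both the tree and a multinomial-logistic
model complements the CV estimate. Metrics: balanced accuracy (mean
per-class recall), support-weighted precision/recall/F1, and a coefficient
of determination computed on integer-coded labels (PersLow 0, PersNorm 1,
PersHigh 2) floored at zero — $R^2$ on a categorical target is ill-posed,
and the flooring convention is kept explicit. Decision-tree hyperparameters
are not pinned by the method; the defaults here (`cp = 0.001`,
`minsplit = 5`, unlimited practical depth) approximate an unpruned
CART fit and are exposed in `classifier_config()`.

**Regression.** Per fold, a 1000-tree random forest (impurity importance,
all 69 features considered at every split — the convention of the reference
implementation this analysis follows) ranks features; those with normalized
importance ≥ 0.005 are kept; gradient-boosted trees (max depth 6, 100
rounds, learning rate 0.1) are fit on the kept features. The population
model is evaluated leave-one-person-out; the personalized model trains on
the first contiguous half of each participant's rows (split at ⌈n/2⌉) and
tests on the rest, with feature selection performed per participant. Naive
mean and median predictors run under identical folds as baselines. Metrics:
RMSE (mg/dL), MAPE (%), accuracy = 100 − MAPE. Predictions are unclipped by
default; `regressor_config(clip = c(40, 400))` enables physiological
clipping.

**Importance analysis.** Each fold's impurity importances are normalized to
sum to 1; means ± sd across folds are aggregated along the three taxonomy
axes as percents of total importance (each axis sums to 100%). Because the
LOPOCV selection forests are exactly the forests this analysis needs,
`importance_from_report()` reuses them; `lopocv_importances()` recomputes
them independently, and a test asserts the two routes agree.

## The synthetic cohort

No raw cohort from the motivating study is publicly deposited, so the
package ships a generator whose defaults encode the study's stated
conditions: 16 participants, 8–10 days of wear, heart rate at 1 Hz, EDA and
skin temperature at 4 Hz, accelerometry at 32 Hz (stored as integer 1/64 g
counts, as the device exports), glucose every 5 minutes, and a wear-gap
fraction (0.42) that leaves roughly 1500 glucose points per participant
over a 9-day wear. Glucose is built as

    baseline + circadian sinusoid + sum of meal kernels
             + sum of activity dips + AR(1) noise,  clipped to [40, 300]

with per-participant baselines ~N(110, 8) mg/dL, an 8 mg/dL circadian
amplitude peaking at 16:00, a log-normal-shaped meal kernel (mode 30 min)
scaled linearly by sugar and carbohydrate grams, and a rectangular
activity-induced dip with exponential recovery. Heart rate and
accelerometry are elevated during planted bouts; the EDA trace carries
planted bursts of skin-conductance-response-shaped peaks with amplitudes
centered on 0.5 µS; inter-beat intervals are paced by the heart-rate trace
with 4% multiplicative jitter so HRV metrics are non-degenerate. All
randomness flows from one seed, with per-participant substreams keyed by
fixed offsets so records are reproducible under cohort-size changes.
`planted_truth()` exposes the planted meal, bout and stress windows for
validating detectors.

The magnitudes are physiological stand-ins — the study reports no
distributional parameters of its raw streams — and the generator makes no
attempt at insulin kinetics, dawn phenomenon, sensor drift, motion artifact
or compression lows. Consequently, passing tests demonstrate that the
pipeline recovers structure *of the kind it assumes* (meal-driven rises,
activity dips, circadian baseline) without leakage; they say nothing about
accuracy on real physiology, where effect sizes, confounding and artifact
structure are harsher.

## Problem sizes and numerical choices

The test suite and the acceptance script exercise effect recovery on a
cohort of 4 participants × 3 days at full device sampling rates, with
strengthened meal (1.0 mg/dL per g sugar) and activity (25 mg/dL dips, 4
bouts/day) effects, low AR(1) noise (sd 1), and a 0.3 wear-gap — roughly
1600 feature rows. This scale was chosen so that the complete pipeline,
including eight 1000-tree full-feature forests, runs comfortably on a
single CPU; the methods themselves are size-agnostic and the generator's
defaults remain the study-scale conditions. Determinism of the full
pipeline is asserted by running it twice at a reduced sampling scale and
comparing artifact files byte for byte.

Other conventions fixed here: quartiles use linear interpolation of order
statistics (matched by the test oracles); rolling statistics are computed by
direct per-window summation so they agree exactly with brute-force
recomputation; EDA-peak candidates on plateaus take the plateau's first
sample; elimination ties drop the later column, and importance ties rank by
feature name, so every ranking is deterministic; xgboost and ranger run
single-threaded with derived seeds (`seed + fold`), which, with fixed fold
assignments, makes every report reproducible to the byte.

## Known limitations

* The wake-time detector assumes one sleep–wake transition per calendar
  day; shift work, naps and fragmented sleep will confuse it, and its first
  day never yields a value.
* The personalization feature is an arbitrary numeric id; for an unseen
  participant (the LOPOCV setting) tree models can only extrapolate from
  neighboring ids, which is meaningless — it helps only where training and
  test people overlap, as in the personalized model.
* With few participants, leave-one-person-out estimates are dominated by
  between-person baseline shifts; the naive mean is then a strong baseline,
  and cohort-level conclusions should rest on larger simulations.
* The KS statistic for class normality uses parameters fitted from the same
  sample, so it is descriptive, not a calibrated test.
* Undersampling before (rather than within) cross-validation follows the
  described procedure but lets fold assignment see the class-balancing
  draw; the alternative is exposed by calling `balance_classes()` inside a
  custom loop.
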