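---
title: "Movement-element decomposition of reaching kinematics: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement-element decomposition of reaching kinematics: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(movelem)
library(dplyr)
```

## The measurement problem

Cerebellar ataxia produces reaching movements that are segmented,
oscillatory and dysmetric. Clinical severity is scored on semi-quantitative
scales such as the Brief Ataxia Rating Scale (BARS, 0-30 in half points),
which require an in-person examination by a specialist. `movelem`
implements a wearable-sensor alternative: a wrist accelerometer records a
repeated nose-to-target reaching task (the finger-to-nose test, FNT), the
velocity time-series is decomposed into *movement elements* -- 1D
sub-movements between consecutive velocity zero-crossings on each body
axis -- and engineered features of those elements feed leave-one-subject-out
(LOSO) Gaussian-process models that estimate severity and classify
phenotype.

Because clinical recordings cannot be redistributed, the package ships a
synthetic cohort generator that plays the role of the study population.
Everything downstream of the generator treats its output exactly as it
would treat real sensor data.

## Signal chain

1. **Gravity removal and smoothing.** The per-axis mean of the raw
   recording estimates the gravity vector; after subtraction, a sixth-order
   zero-phase Butterworth low-pass at 20 Hz removes non-human content.
   Zero-phase (forward-backward) filtering is used because segmentation
   boundaries are zero-crossings: phase distortion would move them.
2. **Integration and drift removal.** Filtered acceleration is
   trapezoidally integrated to velocity; a sixth-order zero-phase band-pass
   (0.1-20 Hz) removes integration drift. The band-pass is designed as
   `butter(3, c(low, high))`, which yields an order-6 band-pass transfer
   function (the convention in which a band-pass doubles the prototype
   order). Whether each axis is filtered before or after axis alignment is
   immaterial because rotation is linear; a unit test asserts the two
   orders agree to 1e-9.
3. **Anatomical axis alignment.** The rostrocaudal (RC) axis is the
   gravity direction; the anteroposterior (AP) axis is the first principal
   direction of the velocity in the gravity-orthogonal plane (seated
   reaching towards a target in the mid-sagittal plane makes AP the
   dominant direction of motion); mediolateral (ML) completes the triad.
   PCA is applied in the gravity-orthogonal plane rather than in raw 3D so
   that RC and AP are exactly orthogonal. Principal directions leave the AP
   sign arbitrary, so the sign is fixed by requiring the single
   largest-distance excursion -- the full reach -- to be positive.
4. **Segmentation.** Each axis is segmented independently at its velocity
   zero-crossings. An exact-zero sample closes the element on its left;
   leading/trailing partial lobes are kept. Elements strictly smaller than
   1 mm or strictly shorter than 5 ms are excluded as potential sensor
   noise (elements exactly at a threshold are retained).

Per element the package records duration, signed distance (trapezoidal
integral of velocity), unsigned distance, and mean speed. Note that with
discrete samples the trapezoid spans `n - 1` intervals while the duration
convention counts `n` sample periods; the resulting mean-speed bias is
below one part in the element length and identical across participants, so
no feature is affected differentially.

## Features (53 by default)

Movement elements from both hands are pooled per participant-visit.

* **Size/speed/duration (27).** Nine aggregations (mean, SD, min, max,
  range, IQR, median, p10, p90; percentiles by linear interpolation,
  type-7) of duration, log distance and log mean speed. Natural logarithms
  are used throughout; the power-law slope is base-invariant but
  aggregations of logs are not, so the base is documented here.
* **Power-law exponent (1).** In unimpaired reaching, mean speed and
  distance couple as `vbar ~ D^(2/3)`. The exponent `alpha` is the OLS
  slope of log mean speed on log distance; it falls with severity because
  impaired reaching is disproportionately slow over large distances.
* **Consecutive-distance ratios (9).** Aggregations of
  `log(D[i+1]/D[i])` within each (hand, axis) stream: spread here means
  inconsistent consecutive sub-movement sizes.
* **Transitions between small elements (4).** A normalized 2D histogram of
  the signed distances of temporally adjacent AP elements (prior vs
  subsequent), binned at 0.02 m over +/-0.46 m; the features are the
  central cells where both elements are at most 0.02 m in magnitude, i.e.
  the probability of chains of small corrective movements (dysmetria).
  Transition features use the AP axis only because the diagnostic
  alternating-reach structure ("towards the tablet") is an AP phenomenon;
  all other feature groups pool the three axes.
* **Morphology (18, minus exclusions).** Every retained element with at
  least two samples is sign-flipped to a positive lobe, divided by its mean
  speed and linearly resampled to 60 points (unit mean restored after
  resampling). A two-component PCA summarizes the 60-dimensional shapes in
  a leave-one-subject-out manner: each participant's scores come from a
  basis fitted on everyone else, so the morphology features of a held-out
  participant never reflect their own data. PC signs are fixed by making
  each loading's largest-magnitude coordinate positive. Nine aggregations
  of PC1 and PC2 scores give 18 features.

The enumeration above totals 59. The default configuration drops six --
the min and max of duration, log distance and log speed -- because those
extremes sit against the 1 mm / 5 ms exclusion boundary or are set by a
single outlier element, leaving 53. The exclusion list and the
small-region size are configuration values
(`default_feature_exclusions()`, arguments of `transition_features()`),
and the count is asserted in tests as a configuration property, not
hard-coded arithmetic.

## Models

`loso_regress()` and `loso_classify()` implement one fold per participant
(all visits held out together, as required for test-retest analysis). Per
fold, features are min-max scaled to [0, 1] and labels z-scored using the
training rows only; out-of-range test values are deliberately not clipped.
The learner is a Gaussian process with an RBF kernel (kernlab); the kernel
width comes from the median-quantile heuristic (`sigest`) computed on the
training fold with a fold-derived seed, making every estimate reproducible
from a single configuration seed. Pediatric participants and participants
whose labels live on a different scale (the parkinsonism group's
UPDRS-like score) are excluded from training folds but still receive
estimates. Training labels with zero variance short-circuit to a constant
prediction.

## Evaluation statistics

`rmse()`, `auc_ci()` (Mann-Whitney AUC, participant-level bootstrap
percentile CI with a fixed seed -- the CI method is a package choice),
`icc31()` (two-way mean squares with the F-based CI), `welch_anova()`,
`games_howell()` (Welch pairwise t referred to the studentized range,
`ptukey`), `welch_t()`, `one_sample_t()` and `pearson_cor()`. A constant
delta vector equal to the null mean returns t = 0, p = 1 ("no change")
rather than an error. Every statistic is tested against an independently
coded direct-formula oracle.

## The synthetic cohort generator

The generator emits raw sensor-frame accelerometry so the full chain --
including gravity estimation and axis recovery -- is exercised. One hand's
recording is a schedule of reach movements alternating towards and away
from the target every few seconds for 40 s, with the target side switching
every 10 s. Each movement has components on all three body axes (defaults:
0.45 m AP, 0.06 m ML, 0.12 m RC). A movement on one axis is a train of
velocity lobes; a lobe is a Beta-density shape (the minimum-jerk profile is
exactly Beta(3, 3)) scaled so mean speed follows the anchored power law

`vbar = k * a0^(2/3) * (D / a0)^alpha(s)`,

with gain `k = 1` SI, anchor `a0 = 0.02` m, and exponent falling linearly
from 2/3 at severity 0 to 0.4 at severity 30. The anchor keeps small
corrective movements near healthy speeds while large reaches slow with
severity, which is what drives the measured exponent down.

Severity `s` (0-30, a BARS analogue) shapes the signal as follows (rates
are defaults; all constants live in `sim_params()`):

* reaches split into `1 + Poisson(3 s/30)` sub-lobes with lognormally
  decaying distance weights;
* `Poisson(0.05 + 3 (s/30)^2)` dysmetric reversal pairs (a small opposite
  lobe plus its correction, ~1 cm) are injected near the endpoint;
* small settling lobes (~4 mm, alternating sign) follow each movement --
  mostly on ML/RC (rate 2.2 per axis) with a lower AP rate (0.5), since
  they model chiefly postural corrections off the reaching axis; their
  rate grows and size shrinks with severity;
* lobe shapes skew and become multi-peaked with probability increasing in
  severity (lognormal jitter of the Beta parameters, clamped above 1 so
  the density stays finite);
* participants with severity < 8 converge to near-minimum-jerk shapes in
  the second half of the task (motor optimization); more severe
  participants do not converge and show a mild fatigue-driven increase in
  shape variability instead.

The parkinsonism group is slow (speed x 0.55) and small (amplitude x 0.75)
but smooth: single lobes, no severity-driven splitting or reversals.
Pediatric participants have amplitudes scaled by 0.8. The composite
body-frame velocity is differentiated, rotated by a per-participant random
mount rotation (SD 6 degrees), gravity is added on the body RC axis and
rotated with the frame, and white noise (SD 0.03 m/s^2, a typical
consumer-IMU accelerometer noise floor) is applied at 128 Hz. The
synthetic clinical score is severity plus rater noise (SD 1 BARS point)
rounded to half points; parkinsonism participants get an unrelated
UPDRS-like score.

Rates and pause lengths were set so that a healthy participant yields on
the order of 430-450 retained elements across both hands and three axes,
matching the element counts typical of real 40-s FNT recordings, and so
that group-level trends are monotone in severity: retained-element count
up, median and mean log distance down, small-transition probability up,
fitted exponent down. These are the fixed study conditions for all tests.

What the generator does **not** emulate: tremor spectra and their
frequency structure, gyroscope/magnetometer channels, age- and arm-length
effects on element distances, tablet touch events, and any non-FNT task.
Passing tests therefore demonstrate that the pipeline recovers the
structure this generative model encodes -- power-law coupling, severity
monotonicity, morphology convergence -- not that it reproduces clinical
effect sizes. In particular the synthetic regression r^2 and AUCs are
optimistic relative to a real cohort because the generator's severity
signal is not confounded by age, diagnosis heterogeneity or comorbid
tremor.

## Numerical choices and degenerate inputs

* Filter warm-up: recordings shorter than three filter lengths are
  rejected; residual post-filter means (edge transients) are subtracted so
  filtered acceleration is exactly zero-mean.
* An all-zero velocity axis yields zero elements; a velocity series with
  no variance off the gravity axis raises a "degenerate recording" error.
* `aggregate_stats()` defines the SD of a single value as 0; empty inputs
  error.
* The power-law fit refuses element sets whose distances are all equal.
* A transition table with fewer than two elements per hand warns and
  returns zero features.
* Elements with a single sample are excluded from morphology scoring
  (a one-point profile has no shape); LOSO PCA requires at least three
  participants and falls back to a common basis below that, with the
  limitation documented.
* Half-task comparisons skip participant-hands with fewer than two
  elements in either half (with a warning).

## Half-task morphology comparison

For each participant-hand, the SD of PC1 scores, SD of PC2 scores and the
mean coefficient of determination against the minimum-jerk reference are
computed for the first and last 20 s; one-sample t-tests on the
second-minus-first deltas identify group-level change. The reference shape
is injectable (`half_test_comparison(reference = ...)`); the packaged
default is the minimum-jerk profile `30 t^2 (1 - t)^2`, the standard
theoretical optimum for point-to-point reaching. The r^2 is computed on
spatially normalized profiles without further amplitude rescaling; with
unit-mean profiles the two conventions differ only by a per-element scale
that the normalization has already removed.

One caveat found during development and worth knowing when interpreting
half-task deltas on any data: because movements front-load their large
lobes and trail small corrective ones, a half boundary that cuts a
movement donates trailing small elements to the second half. This
composition shift biases the pooled SD of PC scores slightly downward in
the second half even without any change in lobe shapes. The generator's
fatigue term for impaired participants counteracts the bias in the
synthetic study conditions; on real data the same caveat argues for
interpreting only the *contrast* between groups, not the absolute delta of
a single group.

## Problem sizes

The test suite and the acceptance script use 40-s, 128-Hz recordings
throughout. Power-law recovery uses 20 healthy participants; severity
monotonicity uses 10 participants per severity level {0, 8, 16, 24}; the
end-to-end modeling study uses 30 healthy, 60 ataxia (10 with a repeat
visit) and 20 parkinsonism participants. These sizes mirror a realistic
single-site study and keep a full run in the low minutes on one core.
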