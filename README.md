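# movelem

Movement-element decomposition of wrist kinematics for objective ataxia
assessment.

Cerebellar ataxia makes goal-directed reaching segmented, oscillatory and
dysmetric, but quantifying that impairment currently requires an in-person
exam scored on semi-quantitative scales such as the Brief Ataxia Rating
Scale (BARS, 0–30). `movelem` implements a digital-biomarker pipeline for
the instrumented finger-to-nose test (FNT): a wrist accelerometer records
~40 s of repeated nose-to-target reaches per hand; the acceleration is
filtered, integrated and rotated into anatomical axes; each axis's velocity
is decomposed into **movement elements** — 1D sub-movements between
consecutive velocity zero-crossings — and per-participant features of those
elements drive leave-one-subject-out (LOSO) Gaussian-process models of
clinical severity and phenotype.

At its core are a small number of interpretable kinematic quantities. Each
retained element (distance ≥ 1 mm, duration ≥ 5 ms) contributes its
duration, distance *D* and mean speed *v̄*. In unimpaired reaching these
couple through the two-thirds power law

> *v̄* ∝ *D*^α,  α = 2/3,

and α — the OLS slope of log *v̄* on log *D* — falls with ataxia severity.
Further features capture the probability of consecutive small corrective
movements (a 2D transition histogram of signed distances), the consistency
of consecutive element sizes (log distance ratios), and the morphology of
unit-mean, 60-sample velocity profiles summarized by leave-one-subject-out
PCA against the minimum-jerk ideal 30 τ²(1−τ)².

Because clinical recordings cannot be shipped, the package includes a
first-class synthetic cohort generator (`simulate_cohort()`) whose output
is raw sensor-frame accelerometry with gravity, mount misalignment and
sensor noise; every downstream stage treats it exactly like real data.

## Worked example

```r
library(movelem)
library(dplyr)

cohort   <- simulate_cohort(n_healthy = 6, n_ataxia = 10, seed = 2024)
elements <- decompose_cohort(cohort)
select(elements, participant_id, hand, axis, start_time_s,
       duration_s, distance_m, mean_speed_ms)
#> # A tibble: 8,586 × 7
#>   participant_id hand  axis  start_time_s duration_s distance_m mean_speed_ms
#>   <chr>          <chr> <chr>        <dbl>      <dbl>      <dbl>         <dbl>
#> 1 P001           left  AP           0          0.297    0.0149         0.0503
#> 2 P001           left  AP           0.297      0.797    0.431          0.541
#> 3 P001           left  AP           1.09       1.48     0.530          0.359
#> 4 P001           left  AP           2.64       0.375    0.00912        0.0243
```

Each row is one sub-movement; the 0.43–0.53 m elements are full reaches,
the millimetre-scale ones are corrective or settling movements. The healthy
speed–distance coupling is recovered per participant:

```r
fit_power_law(filter(elements, participant_id == "P001"))
#> Speed-distance power law: alpha = 0.637 (n = 435)
```

α ≈ 0.64 with 435 elements from 80 s of reaching — close to the theoretical
2/3 for an unimpaired participant. The full feature table (53 features per
participant-visit) and the LOSO models:

```r
feats <- extract_features(elements, metadata = select(cohort, -recording))
est   <- loso_regress(feats)          # severity (BARS-analogue) regression
glance(est)
#> # A tibble: 1 × 3
#>    rmse r_squared     n
#>   <dbl>     <dbl> <int>
#> 1  3.61     0.827    16

cls <- loso_classify(feats)           # ataxia vs healthy
auc_ci(cls$probability, cls$truth, seed = 1)
#> # A tibble: 1 × 4
#>     auc ci_lower ci_upper n_boot
#>   <dbl>    <dbl>    <dbl>  <dbl>
#> 1     1        1        1   2000
```

On this small synthetic cohort the model estimates the generating severity
with an RMSE of 3.6 BARS-analogue points and r² = 0.83, and separates
ataxic from healthy recordings perfectly (AUC 1.0; synthetic severity
signal is unconfounded, so classification is easier than in a clinic).
`run_pipeline(pipeline_config(...))` chains all stages and writes the
manifest, element table, feature table, estimates and a metrics JSON;
`plot_velocity()`, `autoplot()` methods and broom-style `tidy()`/`glance()`
cover inspection.

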