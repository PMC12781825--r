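# timeuse24

Compositional analysis of the 24-hour day — sleep, inactivity, light
activity, and moderate-to-vigorous physical activity (MVPA) — and its
relation to incident dementia and brain volumes. The package is written
for epidemiologists working with accelerometer-derived time use in large
cohorts: because a day is fixed at 1440 minutes, the scientific question
is never "does more MVPA help?" but "more MVPA *instead of what*?", and
the exposure is the whole composition on the simplex.

## What it computes

Time use is mapped to isometric log-ratio (pivot balance) coordinates

```
z1 = sqrt(3/4) ln( p_sleep / (p_inact p_light p_mvpa)^(1/3) )
z2 = sqrt(2/3) ln( p_inact / (p_light p_mvpa)^(1/2) )
z3 = sqrt(1/2) ln( p_light / p_mvpa )
```

and dementia and death hazards are modelled by discrete-time pooled
logistic regressions on person-period data (restricted cubic splines for
continuous predictors; exposure × time, exposure × key-covariate, and
key-covariate × time products). Cumulative dementia incidence under a
time-use regime is the parametric g-formula total effect, with death as a
competing event:

```
F_i(K) = sum_k  hY_i(k) (1 − hD_i(k)) prod_{j<k} (1 − hY_i(j)) (1 − hD_i(j))
```

averaged over a standardization population. On top of that the package
provides:

* **Isotemporal substitution risk ratios** — reallocate 15–60 min/day
  between two behaviours, per sleep-duration subgroup (short < 6 h,
  normal 6–9 h, long > 8 h), with per-person feasibility against the
  sample range and a 75% feasibility rule for presentation.
* **Lowest/typical/highest-risk 24-hour compositions** — a cross-validated
  grid search over a 15-minute lattice with a sample-density
  plausibility filter.
* **MRI g-computation** — mean differences in volumetric outcomes under
  substitutions, and predictions at the selected compositions.
* **Predictive-mean-matching imputation** and **bootstrap percentile
  intervals** (one imputation per bootstrap sample; the person is the
  resampling unit).
* A **synthetic cohort generator** with known ground truth and a
  Monte-Carlo oracle for true risks, so every estimator can be tested
  for recovery.

## Worked example

```r
library(timeuse24)
library(dplyr)

cohort <- simulate_cohort(10000, truth_default(), seed = 42) |>
  trim_extremes() |>
  assign_sleep_group()

round(geometric_mean_composition(cohort) / 60, 2)
#>      sleep_min inactivity_min      light_min       mvpa_min
#>           6.77          11.96           3.56           1.71

rng  <- compute_sample_range(cohort)
fits <- fit_hazard_models(
  expand_person_periods(cohort, K = 9),
  design_spec(covariates = c("age", "female", "apoe4"))
)
tab <- run_substitution_matrix(cohort, fits, K = 9, range = rng,
                               subgroups = c("short", "normal"), deltas = 30)
tab |> select(subgroup, from, to, rr, feasible_fraction, presented)
#> # A tibble: 12 × 6
#>    subgroup from       to            rr feasible_fraction presented
#>  1 short    inactivity sleep      1.00              0.999 TRUE
#>  2 short    sleep      inactivity 1.11              0.968 TRUE
#>  3 short    light      sleep      0.914             0.995 TRUE
#>  4 short    sleep      light      1.29              0.976 TRUE
#>  5 short    mvpa       sleep      1.01              0.933 TRUE
#>  6 short    sleep      mvpa       1.10              0.978 TRUE
#>  7 normal   inactivity sleep      1.07              0.999 TRUE
#>  8 normal   sleep      inactivity 0.919             1.000 TRUE
#>  9 normal   light      sleep      0.966             0.983 TRUE
#> 10 normal   sleep      light      0.975             0.999 TRUE
#> 11 normal   mvpa       sleep      0.967             0.906 TRUE
#> 12 normal   sleep      mvpa       0.778             1.000 TRUE
```

Each row is one reallocation: in this simulated cohort (whose ground
truth makes MVPA protective and very short sleep harmful), moving 30
min/day of sleep into MVPA in normal sleepers multiplies the 9-year
dementia risk by 0.78, while short sleepers gain from extending sleep at
the expense of light activity (RR 0.91). `feasible_fraction` is the share
of the subgroup for whom the substituted day stays inside the sample
range; cells under 75% would be flagged `presented = FALSE`.
`autoplot(tab)` draws the RR-versus-Δ panel grid, and
`bootstrap_substitution_rr()` adds percentile confidence intervals.

The full pipeline — simulation or a cohort CSV, trimming, imputation,
fits, the substitution matrix with bootstrap intervals, the composition
search, and the MRI stage — runs from one configuration object:

```r
report <- run_full_analysis(demo_config(seed = 1))
write_report(report, "demo-results")
```

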