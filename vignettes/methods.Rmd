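---
title: "Methods: compositional time-use analysis of dementia risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compositional time-use analysis of dementia risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(timeuse24)
```

## The problem

A day is 1440 minutes split between sleep, inactivity, light activity, and
moderate-to-vigorous physical activity (MVPA). Because the total is fixed,
"more MVPA" is only meaningful relative to what it displaces: the exposure
is the whole 24-hour *composition*, a point on the 4-part simplex.
`timeuse24` estimates how isotemporal substitutions — moving Δ minutes per
day from one behaviour to another while holding the rest of the day fixed —
shift the cumulative incidence of dementia over roughly eight years of
follow-up, with death treated as a competing event, and how they shift
continuous MRI volumetric outcomes. It also searches a lattice of
synthetic 24-hour days for the compositions with the lowest and highest
model-estimated risk.

## The model

**Coordinates.** Compositions carry only relative information, so they are
mapped to unconstrained coordinates with an isometric log-ratio (pivot
balance) transform. With proportions $p = (p_s, p_i, p_l, p_m)$ in the
order (sleep, inactivity, light, MVPA):

$$
z_1 = \sqrt{\tfrac34}\,\ln\frac{p_s}{(p_i p_l p_m)^{1/3}},\qquad
z_2 = \sqrt{\tfrac23}\,\ln\frac{p_i}{(p_l p_m)^{1/2}},\qquad
z_3 = \sqrt{\tfrac12}\,\ln\frac{p_l}{p_m}.
$$

This sequential binary partition — (sleep | waking), (inactivity |
activity), (light | MVPA) — was chosen so $z_1$ reads as sleep versus the
waking day; any full-rank ILR basis gives identical model fits and risk
estimates (the map between bases is linear), which the test suite verifies
by refitting under a reversed pivot order. The basis is configurable
through `design_spec(contrast = )`. Euclidean distance between ILR images
is the Aitchison distance, the natural metric on the simplex; it is used
for the grid plausibility filter and the typical-composition assignment,
and is the same in every orthonormal basis.

**Hazards.** Follow-up is cut into discrete intervals (default 365.25
days). Person-period rows carry interval-level dementia and death
indicators, and two pooled logistic regressions approximate the
discrete-time hazards $h_Y$ (dementia) and $h_D$ (death). Within an
interval, death is ordered before dementia: a person who dies in interval
$k$ is not at risk of a dementia event in $k$, and the dementia model's
risk set excludes rows with a death that interval. The default design uses
restricted cubic splines (4 knots at the 5/35/65/95 percentiles of the
fitting data, Harrell's truncated-power construction with linear tails) for
time, age, and each ILR coordinate, plus three product blocks —
exposure × time, exposure × key covariates (age, sex, APOE ε4), and key
covariates × time — built linear-by-linear so the interaction surface stays
interpretable and the design desk-scale. Knots and factor levels are
frozen into the fit, so bootstrap replicates and counterfactual
predictions use the same basis.

**G-formula (total effect).** For person $i$ with regime-assigned
coordinates $z_i^*$,

$$
F_i(K) = \sum_{k=1}^{K} h_{Y,i}(k)\,\bigl(1-h_{D,i}(k)\bigr)
\prod_{j<k}\bigl(1-h_{Y,i}(j)\bigr)\bigl(1-h_{D,i}(j)\bigr),
$$

and the reported risk is the mean of $F_i(K)$ over the standardization
population (a sleep-duration subgroup or the full cohort). Death is never
eliminated — it remains a competing event — but both hazards are evaluated
at the regime-modified composition, because an intervention on time use
also shifts the death hazard; this is what makes the estimator consistent
with the simulator's ground truth, where composition physically affects
both processes. Risk ratios divide the substituted by the observed
("natural course") risk at the end of follow-up.

**Regimes and feasibility.** A substitution regime adds Δ to one behaviour
and subtracts Δ from another (Δ ∈ {15, 30, 45, 60} minutes by default). It
is feasible for a person only if the donor behaviour stays positive and
every behaviour of the result lies inside the per-behaviour [min, max] box
of the full trimmed analysis sample. Infeasible persons keep their
observed composition inside the standardization mean (a `"drop"`
alternative excludes them instead; both are exposed because either reading
of "the substitution was not applied for them" is defensible). A
subgroup's cell is *presented* only when at least 75% of the subgroup can
receive the substitution; suppressed cells keep their computed values for
audit. The axis-aligned box was chosen over a joint (convex-hull) region
because it is transparent and auditable; the density filter below supplies
the joint constraint where it matters.

**Sleep subgroups.** Short sleepers sleep under 6 h, normal sleepers
between 6 and 9 h, and the secondary long-sleeper group over 8 h (few
people exceed 9 h, so 8 h is the workable threshold); normal and long
overlap on (8 h, 9 h]. Hazard models are fitted once on the full cohort
and subgroups enter only as standardization populations — the alternative
(refitting within subgroups) is available by filtering before
`fit_hazard_models()`, but the shared fit keeps the substitution contrasts
within subgroups on a common model and is the package default.

**Composition search.** A lattice of synthetic days in 15-minute steps is
enumerated inside the sample range box, and points with fewer than 10
cohort members within Aitchison distance 0.25 are discarded as rare or
implausible (both parameters are configurable and recorded in the output).
Persons are split into two equal folds; the training fold fits the hazard
models and scores every retained lattice point as a fixed-composition
regime; the minimising and maximising points are the lowest- and
highest-risk compositions, the most common point (nearest-neighbour
assignment over the full cohort, ties broken by distance to the
compositional centre then grid order) is the typical composition, and the
testing fold refits and re-estimates the three risks so that selection and
evaluation never share data. On effect-free simulations the training-fold
risk spread exceeds the testing-fold spread — the over-optimism that the
split protects against — and the suite checks this across 20 seeds.

**MRI outcomes.** Volumetric outcomes are modelled by ordinary least
squares on the ILR coordinates, covariates, and imaging covariates
(assessment centre, head motion, head position), restricted to the imaging
substudy; white-matter-hyperintensity volume is analysed on the log scale.
Mean differences under substitutions are computed by g-computation with
the same feasibility and 75% conventions as the dementia models, and
predicted outcomes are reported at the selected lowest/typical/highest
compositions. Head-size normalization is assumed already applied to the
inputs. One subtlety: because the ILR map is nonlinear in minutes, the
mean differences of a substitution and its reverse from a *common*
baseline are only first-order negatives; the exact identities are reversal
evaluated on the substituted cohort and path composition
(A→B then B→C equals A→C), and the tests assert exactly those.

**Missing data and uncertainty.** Covariate missingness is imputed by
predictive mean matching with chained equations (5 donors, 5 cycles,
visit order by ascending missingness; categorical targets are matched on
one-vs-rest linear-predictor scores and copy a donor's category, so
imputations always come from the observed support). Structurally missing
columns — event times without an event, outcomes outside the imaging
substudy — are never imputation targets. Uncertainty is propagated by a
nonparametric bootstrap with the person as the resampling unit and one
imputation per bootstrap sample; intervals are percentile intervals
(`quantile()` type 7), with no BCa correction. `bootstrap_substitution_rr()`
is a specialised fast path for substitution risk ratios that freezes the
design once and warm-starts each replicate's IRLS at the full-sample
coefficients; it is numerically identical to resampling through
`run_substitution_matrix()` and the tests assert the equality.

## The synthetic cohort generator

`simulate_cohort()` draws what the estimators assume: ILR coordinates from
a normal distribution whose mean shifts with age and sex (logistic-normal
compositions, strictly positive by construction), discrete-time dementia
and death events with death drawn first within an interval,
administrative censoring drawn uniformly between 7.3 and 9 years (median
about 8.2), optional Gaussian MRI outcomes linear in the ILR coordinates
within a ~17% imaging substudy, and ~2% MCAR missingness in education and
income (a MAR mechanism patterned on age and sex is available). The
default compositional centre is 6.5 h sleep / 12 h inactivity / 3.3 h
light / 1.7 h MVPA with geometric standard deviations (1.2, 1.1, 1.3, 1.5)
and mild negative inactivity–activity correlations, and the default
dementia hazard is calibrated to ~0.8% cumulative incidence over nine
yearly intervals — the scale of a large community accelerometry cohort in
its seventh decade. Truth hazards may include ILR effects, ILR × time
products, a short-sleep curvature term (per hour below 6 h), and a pure
log-MVPA gradient; coefficients are centred at the compositional centre so
intercepts set the hazard there.

What the generator does *not* emulate: accelerometer measurement noise and
non-wear patterns, cohort self-selection, time-varying behaviour over
follow-up, and informative censoring. Passing tests therefore demonstrate
that the estimators recover the truth of this data-generating process, not
that any real cohort satisfies its assumptions.

`oracle_true_risk()` is the ground truth: it averages the closed-form
discrete-time cumulative incidence over fresh covariate and composition
draws with a regime applied, so estimator error can be measured directly.
Oracle risk ratios use the same seed for numerator and denominator so both
regimes are evaluated on identical draws.

### Calibration presets and their hazard scale

The null-calibration and recovery presets (`truth_null()`,
`truth_protective_mvpa()`, `truth_pattern()`, `truth_mvpa_gradient()`)
deliberately run at elevated baseline hazards (roughly 25–55% cumulative
incidence). The reason is statistical, decided by a power calculation
before any calibration run: at 5000 persons a realistic ~1% incidence
yields ~50 events, and the Fisher information of the pooled logistic fit
then puts the sampling standard deviation of a 30-minute substitution
log-risk-ratio near 0.1 — wider than the ±log(1.08) calibration band
itself, so a null-calibration study at that scale would measure event
sparsity, not estimator bias. At the preset scale (~2900 events at
n = 5000) the same calculation gives a worst-case standard deviation of
about 0.023 before cumulative-incidence damping, placing the band at more
than three standard deviations. The cohort-realistic `truth_default()`
keeps the ~1% scale for descriptive realism and for the end-to-end
demonstration runs.

## Numerical choices

* IRLS convergence at relative deviance change < 1e-10 (1e-8 inside
  bootstrap replicates, warm-started), at most 100 iterations;
  non-convergence is flagged, and prediction from a non-converged fit
  warns.
* Rank-deficient designs are a hard error naming the aliased columns —
  never silent dropping — so bootstrap replicates stay comparable.
* Zero or negative behaviour minutes are rejected, not imputed:
  accelerometry-derived daily averages are effectively never exactly zero,
  and the generator guarantees positivity. Zero-replacement is a
  non-goal.
* Day-level records may total between 1200 and 1680 minutes before
  closure (device non-wear tolerance); weekday/weekend standardization
  weights are 5/7 and 2/7 with a flagged fallback when only one stratum
  was worn, and closure to 1440 happens after weighting.
* Trimming removes persons outside the 0.1st–99.9th percentile of any
  behaviour, with linear-interpolation (type 7) quantiles computed once on
  the input cohort.
* Spline values beyond the boundary knots use the basis's linear tails and
  raise a single extrapolation warning.
* Ties in the typical-composition count break by Aitchison distance to the
  cohort centre, then grid order; `which.min` ties in the risk search
  resolve to the first (lexicographically smallest) lattice point.
* Every stochastic stage takes an explicit seed; identical configurations
  produce byte-identical result files, which the suite checks end to end.

## Problem sizes in the test suite

The suite favours a few deep checks at fixed sizes: the
Aalen–Johansen equivalence gate at n = 200 and K = 5 (agreement to 1e-6);
null calibration over 20 cohorts of 5000 with B = 200 bootstrap
replicates; oracle recovery at n = 20,000 against a 100,000-draw
Monte-Carlo oracle; the composition search at n = 8000 on the full
15-minute lattice plus a 20-seed over-optimism study at n = 2000 on a
30-minute lattice; and a 16-replication interval-coverage study at
n = 2000 with B = 100. These sizes are the package's chosen compromise
between Monte-Carlo precision and a test suite that runs in minutes.

## Interface notes and limitations

The package's interface is its functions: `run_full_analysis()` composes
simulate → prepare → fit → substitutions → composition search → MRI with a
single `run_config()`, and `write_report()` emits hash-stamped CSV/JSON
tables, so no shell-level wrapper is shipped. Sensitivity analyses are
configuration switches: extra covariates (including a sleep-fragmentation
column, if present) enter through `design_spec(covariates = )`, reverse
causation is probed with `truncate_years` (dropping dementia events in the
first years of follow-up), and selection-bias standardization is exposed
as a generic post-stratification hook — `estimate_risk(weights = )`
re-standardizes any risk curve to user-supplied person weights; the
package ships no reference weight table. Known limitations, all
deliberate: censoring is assumed noninformative given covariates (no
IPCW); the exposure is a single baseline composition (point-exposure
g-formula — no time-varying behaviours); product terms are
linear-by-linear; only the total effect with respect to death is
estimated (no separable or controlled direct effects); and penalized or
random-effects hazard models are out of scope.
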