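# Parametric g-formula: closed forms, the nonparametric Aalen-Johansen
# oracle gate, regime mechanics, and invariances.

# Build a hazard_fit by hand with an intercept-only design.
constant_fit <- function(outcome, p) {
  spec <- design_spec(
    covariates = character(0), spline_vars = character(0),
    time_type = "none", exposure_time = FALSE, exposure_key = FALSE,
    key_time = FALSE, exposures = character(0)
  )
  spec$knots <- list()
  spec$levels <- list()
  structure(
    list(
      outcome = outcome, coef = c(`(Intercept)` = qlogis(p)),
      converged = TRUE, loglik = NA_real_, n = 0L, events = 0L, spec = spec
    ),
    class = "hazard_fit"
  )
}

constant_models <- function(pY, pD) {
  structure(
    list(dementia = constant_fit("dementia", pY), death = constant_fit("death", pD)),
    class = "hazard_models"
  )
}

toy_cohort <- function(n = 50) {
  tibble::tibble(
    pid = seq_len(n),
    sleep_min = 400, inactivity_min = 700, light_min = 220, mvpa_min = 120
  )
}

test_that("risk curves obey the closed forms for constant hazards", {
  co <- toy_cohort()
  # zero dementia hazard: F identically (numerically) zero
  r0 <- estimate_risk(co, constant_models(1e-300, 0.1), regime_observed(), K = 6)
  expect_lt(max(r0$risk), 1e-290)

  # no deaths, constant hazard p: F(k) = 1 - (1 - p)^k exactly
  p <- 0.07
  r1 <- estimate_risk(co, constant_models(p, 1e-300), regime_observed(), K = 6)
  expect_equal(r1$risk, 1 - (1 - p)^(1:6), tolerance = 1e-10)

  # monotone nondecreasing and bounded by 1 minus the death mass
  r2 <- estimate_risk(co, constant_models(0.1, 0.05), regime_observed(), K = 8)
  expect_true(all(diff(r2$risk) >= 0))
  expect_lt(r2$risk[8], 1)

  expect_equal(risk_ratio(r2, r2), 1)
  expect_error(risk_ratio(r2, r1[1:3, ]), "same intervals")
  zero_curve <- tibble::tibble(k = 1:6, risk = 0)
  expect_error(risk_ratio(r1, zero_curve), "undefined")
})

test_that("g-formula equals the Aalen-Johansen estimator under saturated models", {
  skip_if_not_installed("survival")
  co <- make_binary_cohort(250, 5,
    hY = function(k, x) plogis(-2.2 + 0.25 * k + 0.5 * x),
    hD = function(k, x) plogis(-2.8 + 0.1 * k - 0.3 * x), seed = 42
  )
  pp <- expand_person_periods(co, interval_days = 1)
  fits <- fit_hazard_models(pp, saturated_spec())
  rc <- estimate_risk(co, fits, regime_observed(), K = 5)

  # independent oracle: multi-state survfit cumulative incidence
  st <- factor(co$status, levels = c("censored", "dementia", "death"))
  aj <- survival::survfit(survival::Surv(co$tk, st) ~ 1)
  aj_dem <- summary(aj, times = 1:5)$pstate[, which(aj$states == "dementia")]
  expect_lt(max(abs(rc$risk - aj_dem)), 1e-6)
})

test_that("regimes modify compositions and account feasibility", {
  co <- tibble::tibble(
    pid = 1:3,
    sleep_min = c(390, 400, 380), inactivity_min = c(720, 700, 740),
    light_min = c(225, 230, 200), mvpa_min = c(105, 110, 120)
  )
  reg <- regime_substitution("light", "sleep", 30)
  ap <- timeuse24:::apply_regime(co, reg)
  expect_equal(ap$sleep_min, co$sleep_min + 30)
  expect_equal(ap$light_min, co$light_min - 30)
  expect_equal(rowSums(as.matrix(ap[behavior_cols()])), rep(1440, 3))

  # infeasible persons keep their observed composition under the default
  rng <- tibble::tibble(
    behavior = behaviors(),
    min = c(380, 650, 150, 50), max = c(425, 750, 260, 150)
  )
  reg2 <- regime_substitution("light", "sleep", 30, range = rng)
  ap2 <- timeuse24:::apply_regime(co, reg2)
  expect_equal(ap2$.feasible, c(TRUE, FALSE, TRUE)) # person 2 would exceed max sleep
  expect_equal(ap2$sleep_min[2], 400)

  # under "drop" the infeasible person leaves the standardization mean
  reg3 <- regime_substitution("light", "sleep", 30, range = rng, infeasible = "drop")
  r_drop <- estimate_risk(co, constant_models(0.05, 0.01), reg3, K = 3)
  expect_equal(attr(r_drop, "n"), 2)
  expect_equal(feasible_fraction(r_drop), 2 / 3)

  fixed <- regime_fixed(c(390, 720, 225, 105))
  ap3 <- timeuse24:::apply_regime(co, fixed)
  expect_true(all(ap3$sleep_min == 390))
  expect_error(regime_substitution("sleep", "sleep", 30), "differ")
  expect_error(regime_substitution("sleep", "mvpa", -15), "positive")
})

test_that("risks are invariant to the ILR basis when the design is rebuilt", {
  co <- simulate_cohort(1500, truth_protective_mvpa(), seed = 44)
  # alternative sequential binary partition: reversed pivot order
  Valt <- ilr_contrast_matrix()[, 4:1]
  co_alt <- co
  co_alt[paste0("z", 1:3)] <- as.data.frame(
    ilr_transform(as.matrix(co[behavior_cols()]), contrast = Valt)
  )
  spec <- light_spec()
  spec_alt <- light_spec()
  spec_alt$contrast <- Valt
  f1 <- fit_hazard_models(expand_person_periods(co, K = 9), spec)
  f2 <- fit_hazard_models(expand_person_periods(co_alt, K = 9), spec_alt)
  r1 <- estimate_risk(co, f1, regime_observed(), K = 9)
  r2 <- estimate_risk(co_alt, f2, regime_observed(), K = 9)
  expect_equal(r1$risk, r2$risk, tolerance = 1e-6)
})

test_that("estimated substitution RRs approach the oracle as n grows", {
  tr <- truth_protective_mvpa()
  reg_for <- function(co) {
    regime_substitution("sleep", "mvpa", 30, range = compute_sample_range(co))
  }
  est_rr <- function(n, seed) {
    co <- assign_sleep_group(simulate_cohort(n, tr, seed = seed))
    fits <- fit_hazard_models(expand_person_periods(co, K = 9), light_spec())
    normal <- co[subgroup_members(co, "normal"), ]
    reg <- reg_for(co)
    rr <- risk_ratio(
      estimate_risk(normal, fits, reg, K = 9),
      estimate_risk(normal, fits, regime_observed(), K = 9)
    )
    oracle <- oracle_true_rr(tr, reg, n_mc = 5e4, seed = 4000, subgroup = "normal")
    abs(log(rr) - log(oracle))
  }
  err_small <- est_rr(2000, seed = 45)
  err_large <- est_rr(50000, seed = 46)
  expect_lt(err_large, err_small)
  expect_lt(err_large, 0.05)
})

test_that("post-stratification weights re-standardize the risk curve", {
  co <- assign_sleep_group(simulate_cohort(1200, truth_null(), seed = 47))
  fits <- fit_hazard_models(expand_person_periods(co, K = 9), light_spec())
  young <- co$age < median(co$age)
  w <- ifelse(young, 2, 1)
  r_w <- estimate_risk(co, fits, regime_observed(), K = 9, weights = w)
  # oracle: weighted mean of per-person risks computed from two subgroup
  # curves mixed with the weight shares
  r_young <- estimate_risk(co[young, ], fits, regime_observed(), K = 9)
  r_old <- estimate_risk(co[!young, ], fits, regime_observed(), K = 9)
  share <- sum(w[young]) / sum(w)
  expect_equal(r_w$risk, share * r_young$risk + (1 - share) * r_old$risk,
    tolerance = 1e-10
  )
  # dementia risk is strongly age-graded, so upweighting the young lowers it
  r_u <- estimate_risk(co, fits, regime_observed(), K = 9)
  expect_lt(r_w$risk[9], r_u$risk[9])
  expect_error(
    estimate_risk(co, fits, regime_observed(), K = 9, weights = rep(-1, nrow(co))),
    "nonnegative"
  )
})
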