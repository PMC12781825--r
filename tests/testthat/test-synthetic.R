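# Synthetic cohort generator: reproducibility, marginal targets, hazard
# mechanics, MRI outcomes, missingness, and the Monte-Carlo risk oracle.

test_that("covariate generation is reproducible with calibrated marginals", {
  expect_error(generate_covariates(0), "at least 1")
  expect_identical(generate_covariates(500, seed = 4), generate_covariates(500, seed = 4))
  big <- generate_covariates(1e5, seed = 1)
  expect_lt(abs(mean(big$female) - 0.56), 0.01)
  expect_true(all(big$apoe4 %in% 0:2))
  expect_true(all(big$age >= 44 & big$age <= 79))
})

test_that("compositions are logistic-normal with covariate-shifted means", {
  covs <- generate_covariates(2000, seed = 2)
  tr <- truth_default()

  # degenerate covariance: every draw equals its conditional mean
  tr0 <- truth_params(ilr_cov = diag(1e-20, 3))
  comp0 <- generate_compositions(covs, tr0, seed = 3)
  mu <- matrix(tr0$ilr_mean, 2000, 3, byrow = TRUE) +
    outer((covs$age - 62) / 8, tr0$covariate_ilr$age_sd) +
    outer(as.numeric(covs$female), tr0$covariate_ilr$female)
  expect_equal(as.matrix(comp0[behavior_cols()]), ilr_inverse(mu),
    tolerance = 1e-6, ignore_attr = TRUE
  )

  # log-normal mean oracle: at large n the geometric-mean composition is
  # within 5% (ratio scale) of the inverse-ILR of the mean coordinate
  covs_big <- generate_covariates(20000, seed = 5)
  comp <- generate_compositions(covs_big, tr, seed = 6)
  gm <- geometric_mean_composition(comp)
  z <- ilr_transform(as.matrix(comp[behavior_cols()]))
  center <- ilr_inverse(colMeans(z))
  expect_true(all(abs(log(gm / center)) < log(1.05)))

  expect_false(identical(
    generate_compositions(covs, tr, seed = 1),
    generate_compositions(covs, tr, seed = 2)
  ))
  expect_error(
    generate_compositions(covs, truth_params(ilr_cov = diag(c(1, 1, -1)))),
    "positive-definite"
  )
})

test_that("event generation follows the configured discrete-time hazards", {
  covs <- generate_covariates(4000, seed = 7)
  tr_none <- truth_params(
    dem = list(intercept = -Inf),
    death = list(intercept = -4)
  )
  co <- add_ilr(dplyr::bind_cols(covs, generate_compositions(covs, tr_none, seed = 8)))
  ev <- generate_events(co, tr_none, seed = 9)
  expect_equal(sum(ev$event_dem), 0)

  # no deaths, constant dementia hazard p, no censoring before K:
  # closed form 1 - (1 - p)^K
  p <- 0.05
  tr_const <- truth_params(
    dem = list(intercept = qlogis(p)),
    death = list(intercept = -Inf),
    censor_years_range = c(9.5, 9.6)
  )
  ev2 <- generate_events(co, tr_const, seed = 10)
  expected <- 1 - (1 - p)^9
  expect_lt(abs(mean(ev2$event_dem) - expected), 3 * sqrt(expected * (1 - expected) / 4000))

  # hidden truth: interval-1 dementia fraction matches the configured hazard
  hidden <- attr(ev2, "hidden")
  h1 <- hidden$h_dem[, 1]
  expect_equal(unique(round(h1, 12)), p)
  first_frac <- mean(hidden$cand_dem == 1)
  expect_lt(abs(first_frac - p), 3 * sqrt(p * (1 - p) / 4000))

  # exactly one first-event type per person, consistent with times
  expect_true(all(ev2$status %in% c("dementia", "death", "censored")))
  expect_equal(ev2$event_dem + ev2$event_death <= 1, rep(TRUE, 4000))
  expect_true(all(ev2$time[ev2$status == "censored"] == ev2$time_censor[ev2$status == "censored"]))
})

test_that("simulated cohorts are byte-identical given the seed and emulate the cohort facts", {
  a <- simulate_cohort(800, truth_default(), seed = 12)
  b <- simulate_cohort(800, truth_default(), seed = 12)
  expect_identical(as.data.frame(a), as.data.frame(b))
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_cohort_csv(a, f1)
  write_cohort_csv(b, f2)
  expect_identical(readLines(f1), readLines(f2))

  big <- simulate_cohort(30000, truth_default(), seed = 13)
  # ~1% cumulative dementia incidence and follow-up a bit over 8 years
  expect_lt(mean(big$event_dem), 0.02)
  expect_gt(mean(big$event_dem), 0.004)
  med_fu <- median(big$time_censor) / 365.25
  expect_gt(med_fu, 7.5)
  expect_lt(med_fu, 9)
  gm <- geometric_mean_composition(big) / 60
  expect_lt(abs(gm[["sleep_min"]] - 6.6), 0.5)
  expect_lt(abs(gm[["inactivity_min"]] - 12.2), 0.6)
})

test_that("MRI outcomes are linear in the ILR coordinates with Gaussian noise", {
  tr <- truth_default()
  co <- simulate_cohort(3000, tr, seed = 14)

  tr0 <- tr
  tr0$mri$imaging_fraction <- 1
  tr0$mri$outcomes$hippocampus_cm3$sd <- 0
  m0 <- generate_mri(co, tr0, seed = 15)
  cf <- tr0$mri$outcomes$hippocampus_cm3
  z <- as.matrix(m0[paste0("z", 1:3)])
  lp <- cf$intercept + as.numeric(z %*% cf$z) +
    cf$age * (m0$age - 62) / 8 + cf$female * m0$female +
    cf$center[match(m0$mri_center, c("A", "B", "C"))] +
    cf$motion * m0$head_motion + cf$head_position * m0$head_position
  expect_equal(m0$hippocampus_cm3, lp, tolerance = 1e-12)

  # OLS recovers the generating coefficients within 3 SE at n = 10^4
  co2 <- simulate_cohort(10000, tr, seed = 16)
  tr1 <- tr
  tr1$mri$imaging_fraction <- 1
  m1 <- generate_mri(co2, tr1, seed = 17)
  fit <- stats::lm(
    hippocampus_cm3 ~ z1 + z2 + z3 + I((age - 62) / 8) + female +
      mri_center + head_motion + head_position,
    data = m1
  )
  est <- summary(fit)$coefficients
  truth_z <- tr1$mri$outcomes$hippocampus_cm3$z
  for (j in 1:3) {
    row <- est[paste0("z", j), ]
    expect_lt(abs(row["Estimate"] - truth_z[j]), 3 * row["Std. Error"])
  }

  m2 <- generate_mri(co, tr, seed = 18)
  expect_lt(abs(mean(m2$imaging) - 0.17), 0.03)
  expect_true(all(is.na(m2$hippocampus_cm3[!m2$imaging])))
  trbad <- tr
  trbad$mri$outcomes$hippocampus_cm3$sd <- -1
  expect_error(generate_mri(co, trbad, seed = 1), "nonnegative")
})

test_that("missingness injection hits its rates under MCAR and is age-patterned under MAR", {
  co <- simulate_cohort(20000, truth_default(), seed = 19)
  expect_identical(
    inject_missingness(co, rates = c(education = 0), seed = 1)$education,
    co$education
  )
  mcar <- inject_missingness(co, rates = c(education = 0.02), seed = 20)
  expect_lt(abs(mean(is.na(mcar$education)) - 0.02), 0.003)

  mar <- inject_missingness(co,
    rates = c(education = 0.05),
    mechanism = "MAR", seed = 21
  )
  older <- co$age > median(co$age)
  expect_gt(
    mean(is.na(mar$education[older])),
    mean(is.na(mar$education[!older]))
  )
  expect_lt(abs(mean(is.na(mar$education)) - 0.05), 0.01)

  expect_error(inject_missingness(co, rates = c(education = 0.7)), "0.5")
  expect_error(inject_missingness(co, rates = c(sleep_min = 0.1)), "never masked")
})

test_that("the Monte-Carlo oracle matches closed forms and scales its error", {
  p <- 0.04
  tr <- truth_params(
    dem = list(intercept = qlogis(p)),
    death = list(intercept = -Inf)
  )
  o <- oracle_true_risk(tr, n_mc = 2e4, seed = 22)
  expect_equal(o$risk, 1 - (1 - p)^9, tolerance = 1e-6)
  expect_equal(o$se, 0) # hazards are covariate-free: no MC variation

  # null truth: substituted and observed risks agree on the same draws
  trn <- truth_null()
  rng <- tibble::tibble(
    behavior = behaviors(), min = c(120, 300, 30, 5), max = c(700, 1100, 600, 500)
  )
  rr <- oracle_true_rr(trn,
    regime_substitution("sleep", "mvpa", 30, rng),
    n_mc = 2e4, seed = 23
  )
  expect_equal(rr, 1, tolerance = 1e-10)

  # quadrupling the draws roughly halves the standard error
  trd <- truth_default()
  se1 <- oracle_true_risk(trd, n_mc = 5000, seed = 24)$se
  se2 <- oracle_true_risk(trd, n_mc = 20000, seed = 25)$se
  expect_lt(se2 / se1, 0.65)
  expect_gt(se2 / se1, 0.35)
})

test_that("truth parameters survive a YAML round trip", {
  tr <- truth_pattern()
  p <- tempfile(fileext = ".yaml")
  write_truth_yaml(tr, p)
  back <- read_truth_yaml(p)
  expect_equal(back$ilr_mean, tr$ilr_mean, tolerance = 1e-12)
  expect_equal(back$ilr_cov, tr$ilr_cov, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$dem, tr$dem, tolerance = 1e-12)
  expect_equal(back$missing$rates, tr$missing$rates)
  # identical cohorts from the original and the round-tripped truth
  a <- simulate_cohort(300, tr, seed = 26)
  b <- simulate_cohort(300, back, seed = 26)
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = 1e-12)
})
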