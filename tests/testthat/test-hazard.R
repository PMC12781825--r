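# Discrete-time survival machinery: person-period expansion, spline
# bases, design construction, and pooled logistic fits.

test_that("person-period expansion places rows and indicators correctly", {
  co <- tibble::tibble(
    pid = 1:3,
    sleep_min = 400, inactivity_min = 700, light_min = 220, mvpa_min = 120,
    event_dem = c(0L, 1L, 0L),
    time_dem = c(NA, 1.6, NA),
    event_death = c(0L, 0L, 1L),
    time_death = c(NA, NA, 3.2),
    time_censor = c(3, 5, 9)
  )
  pp <- expand_person_periods(co, interval_days = 1)
  # person 1: censored in interval 3 -> 3 rows, all indicators zero
  p1 <- pp[pp$pid == 1, ]
  expect_equal(nrow(p1), 3)
  expect_equal(sum(p1$dementia) + sum(p1$death), 0)
  # person 2: dementia in interval 2 -> 2 rows, dementia = 1 only in k = 2
  p2 <- pp[pp$pid == 2, ]
  expect_equal(nrow(p2), 2)
  expect_equal(p2$dementia, c(0L, 1L))
  # person 3: death in interval 4
  p3 <- pp[pp$pid == 3, ]
  expect_equal(nrow(p3), 4)
  expect_equal(p3$death, c(0L, 0L, 0L, 1L))
  expect_true(all(c("z1", "z2", "z3") %in% names(pp)))

  bad <- co
  bad$time_censor[1] <- -1
  expect_error(expand_person_periods(bad, interval_days = 1), "nonnegative")
})

test_that("expansion row count matches a naive per-person loop on simulated data", {
  co <- simulate_cohort(1000, truth_null(), seed = 30)
  pp <- expand_person_periods(co, K = 9)
  # brute-force oracle
  expected <- 0L
  for (i in seq_len(nrow(co))) {
    t_dem <- if (co$event_dem[i] == 1) co$time_dem[i] else Inf
    t_death <- if (co$event_death[i] == 1) co$time_death[i] else Inf
    tt <- min(t_dem, t_death, co$time_censor[i])
    expected <- expected + min(9L, as.integer(ceiling(tt / 365.25)))
  }
  expect_equal(nrow(pp), expected)
  # at most one event indicator per person, in the final row only
  per <- dplyr::summarise(dplyr::group_by(pp, pid),
    n_ev = sum(dementia + death),
    last_ok = all(which(dementia == 1 | death == 1) == dplyr::n()),
    .groups = "drop"
  )
  expect_true(all(per$n_ev <= 1))
  expect_true(all(per$last_ok))
})

test_that("restricted cubic spline basis is linear-tailed and C2-smooth", {
  knots <- c(1, 3, 5, 8)
  expect_equal(ncol(rcs_basis(0:10, c(1, 5, 8))), 2)
  expect_error(rcs_basis(0:10, c(1, 1, 5)), "strictly increasing")
  expect_error(rcs_basis(0:10, c(5, 2)), "3 knots")

  # below the first knot every nonlinear column vanishes (left-linear tail)
  left <- rcs_basis(seq(-5, 0.99, by = 0.01), knots)
  expect_true(all(left[, -1] == 0))

  # second differences on a fine grid: continuous across knots, zero
  # beyond the boundary (linearity)
  h <- 1e-3
  x <- seq(0, 10, by = h)
  b <- rcs_basis(x, knots)
  for (j in 2:ncol(b)) {
    d2 <- diff(b[, j], differences = 2) / h^2
    expect_lt(max(abs(diff(d2))) * h, 1e-2) # no jumps: d2 is continuous
    right <- x[-c(1, length(x))] > 8 + h
    expect_lt(max(abs(d2[right])), 1e-6)
  }
})

test_that("build_design has the declared columns, products, and determinism", {
  pp <- expand_person_periods(simulate_cohort(300, truth_null(), seed = 31), K = 9)
  pp$grp <- rep(c("a", "b"), length.out = nrow(pp))

  spec <- design_spec(
    covariates = "grp", key_covariates = character(0),
    spline_vars = character(0), time_type = "linear",
    exposure_time = FALSE, exposure_key = FALSE, key_time = FALSE
  )
  X <- build_design(pp, spec)
  # intercept + k + z1..z3 + one dummy
  expect_equal(colnames(X), c("(Intercept)", "k", "z1", "z2", "z3", "grpb"))

  spec2 <- design_spec(
    covariates = c("age", "female"), key_covariates = "female",
    spline_vars = character(0), time_type = "linear",
    exposure_time = TRUE, exposure_key = TRUE, key_time = TRUE
  )
  X2 <- build_design(pp, spec2)
  expect_equal(X2[, "z1:k"], X2[, "z1"] * X2[, "k"], ignore_attr = TRUE)
  expect_equal(X2[, "z2:female"], X2[, "z2"] * as.numeric(pp$female), ignore_attr = TRUE)
  expect_equal(X2[, "female:k"], as.numeric(pp$female) * X2[, "k"], ignore_attr = TRUE)
  expect_identical(X2, build_design(pp, spec2))
})

test_that("pooled logistic fits are exact ML with invariances", {
  co <- make_binary_cohort(300, 5,
    hY = function(k, x) 0.08 + 0.02 * x,
    hD = function(k, x) 0.05, seed = 32
  )
  pp <- expand_person_periods(co, interval_days = 1)

  # intercept-only: the fitted hazard is exactly the empirical event
  # fraction among at-risk rows (Bernoulli MLE)
  spec0 <- design_spec(
    covariates = character(0), spline_vars = character(0),
    time_type = "none", exposure_time = FALSE, exposure_key = FALSE,
    key_time = FALSE, exposures = character(0)
  )
  fit0 <- fit_pooled_logistic(pp, "dementia", spec0)
  emp <- mean(pp$dementia[pp$death == 0])
  expect_equal(plogis(unname(fit0$coef[1])), emp, tolerance = 1e-10)
  fit0d <- fit_pooled_logistic(pp, "death", spec0)
  expect_equal(plogis(unname(fit0d$coef[1])), mean(pp$death), tolerance = 1e-10)

  # duplication invariance: doubling every row leaves estimates unchanged
  spec <- saturated_spec()
  f1 <- fit_pooled_logistic(pp, "dementia", spec)
  f2 <- fit_pooled_logistic(dplyr::bind_rows(pp, pp), "dementia", spec)
  expect_equal(f1$coef, f2$coef, tolerance = 1e-6)

  # permutation invariance
  perm <- withr::with_seed(33, sample(nrow(pp)))
  f3 <- fit_pooled_logistic(pp[perm, ], "dementia", spec)
  expect_equal(f1$coef, f3$coef, tolerance = 1e-8)

  # fitting improves on the null model's log-likelihood
  expect_gt(f1$loglik, with(
    list(y = pp$dementia[pp$death == 0]),
    sum(y * log(mean(y)) + (1 - y) * log(1 - mean(y)))
  ) - 1e-9)

  # rank deficiency is a hard, named error
  ppx <- dplyr::mutate(pp, dupe = as.numeric(x))
  spec_dup <- design_spec(
    covariates = c("x", "dupe"), key_covariates = character(0),
    spline_vars = character(0), time_type = "linear",
    exposure_time = FALSE, exposure_key = FALSE, key_time = FALSE,
    exposures = character(0)
  )
  expect_error(fit_pooled_logistic(ppx, "dementia", spec_dup), "rank deficient")

  # zero events is an explicit error
  pp_noev <- dplyr::mutate(pp, dementia = 0L)
  expect_error(fit_pooled_logistic(pp_noev, "dementia", spec), "no dementia events")
})

test_that("saturated fits reproduce empirical interval-specific hazards exactly", {
  co <- make_binary_cohort(400, 4,
    hY = function(k, x) plogis(-2 + 0.3 * k + 0.6 * x),
    hD = function(k, x) plogis(-2.5 - 0.2 * x), seed = 34
  )
  pp <- expand_person_periods(co, interval_days = 1)
  fit <- fit_pooled_logistic(pp, "dementia", saturated_spec())
  at_risk <- pp[pp$death == 0, ]
  emp <- dplyr::summarise(dplyr::group_by(at_risk, k, x),
    emp = mean(dementia), n = dplyr::n(), .groups = "drop"
  )
  pred <- predict_hazard(fit, emp)
  expect_equal(pred, emp$emp, tolerance = 1e-7)
})

test_that("fits recover generating coefficients within 3 SE on large samples", {
  # simulate person-periods directly from a known logistic hazard
  n <- 50000
  withr::with_seed(35, {
    x1 <- rnorm(n)
    x2 <- rbinom(n, 1, 0.4)
    eta <- -2.5 + 0.6 * x1 - 0.8 * x2
    y <- rbinom(n, 1, plogis(eta))
  })
  X <- cbind(`(Intercept)` = 1, x1 = x1, x2 = x2)
  fit <- timeuse24:::fit_logistic_core(X, y)
  W <- plogis(X %*% fit$coef)
  info <- crossprod(X * sqrt(as.numeric(W * (1 - W))))
  se <- sqrt(diag(solve(info)))
  truth <- c(-2.5, 0.6, -0.8)
  expect_true(all(abs(fit$coef - truth) < 3 * se))
})

test_that("predict_hazard is the inverse-logit of the frozen design", {
  pp <- expand_person_periods(simulate_cohort(500, truth_null(), seed = 36), K = 9)
  spec <- light_spec()
  fit <- fit_pooled_logistic(pp, "dementia", spec)

  # manual dot product + expit oracle on a hand-built row
  row <- pp[7, ]
  X <- build_design(row, fit$spec)
  expect_equal(
    predict_hazard(fit, row),
    as.numeric(plogis(X %*% fit$coef)),
    tolerance = 1e-12
  )

  # all-zero coefficients give 0.5; intercept-only structure is constant
  fit0 <- fit
  fit0$coef[] <- 0
  expect_equal(predict_hazard(fit0, pp[1:5, ]), rep(0.5, 5))
  fit1 <- fit
  fit1$coef[] <- 0
  fit1$coef["(Intercept)"] <- qlogis(0.2)
  expect_equal(predict_hazard(fit1, pp[1:8, ]), rep(0.2, 8), tolerance = 1e-12)

  # splined variables outside their boundary knots warn once
  spec_s <- design_spec(
    covariates = "age", key_covariates = character(0),
    spline_vars = "age", time_type = "linear",
    exposure_time = FALSE, exposure_key = FALSE, key_time = FALSE
  )
  fit_s <- fit_pooled_logistic(pp, "dementia", spec_s)
  far <- dplyr::mutate(pp[1:2, ], age = 200)
  expect_warning(predict_hazard(fit_s, far), "boundary")
})
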