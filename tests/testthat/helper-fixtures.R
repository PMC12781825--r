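# Shared fixtures: all data is built in code at test time.

# A lean hazard-model design used where the test is about the estimator
# machinery rather than the design surface.
light_spec <- function(covariates = c("age", "female", "apoe4")) {
  design_spec(
    covariates = covariates,
    spline_vars = character(0), time_type = "linear",
    exposure_time = FALSE, exposure_key = FALSE, key_time = FALSE
  )
}

# Hand-rolled discrete-time cohort with one binary covariate and known
# interval hazards (functions of k and x), death drawn before dementia,
# administrative censoring at K. Times are in "days" with one-day
# intervals so interval index == day.
make_binary_cohort <- function(n, K, hY, hD, seed = 1) {
  withr::with_seed(seed, {
    x <- rbinom(n, 1, 0.5)
    status <- character(n)
    tk <- numeric(n)
    for (i in seq_len(n)) {
      s <- "censored"
      t <- K
      for (k in seq_len(K)) {
        if (runif(1) < hD(k, x[i])) {
          s <- "death"
          t <- k
          break
        }
        if (runif(1) < hY(k, x[i])) {
          s <- "dementia"
          t <- k
          break
        }
      }
      status[i] <- s
      tk[i] <- t
    }
    tibble::tibble(
      pid = seq_len(n), x = x,
      sleep_min = 400, inactivity_min = 700, light_min = 220, mvpa_min = 120,
      event_dem = as.integer(status == "dementia"),
      time_dem = ifelse(status == "dementia", tk - 0.5, NA_real_),
      event_death = as.integer(status == "death"),
      time_death = ifelse(status == "death", tk - 0.5, NA_real_),
      time_censor = K,
      status = status, tk = tk
    )
  })
}

# Saturated design over interval x binary covariate (one parameter per
# cell), for the nonparametric-equivalence tests.
saturated_spec <- function() {
  design_spec(
    covariates = "x", key_covariates = "x",
    spline_vars = character(0), time_type = "factor",
    exposure_time = FALSE, exposure_key = FALSE, key_time = TRUE,
    exposures = character(0)
  )
}

# Random strictly positive compositions closed to 1440.
random_compositions <- function(n, seed = 1, sd = 0.6) {
  withr::with_seed(seed, {
    z <- matrix(rnorm(n * 3, sd = sd), ncol = 3)
  })
  tibble::as_tibble(as.data.frame(ilr_inverse(z)))
}

expect_composition_equal <- function(actual, expected, tol = 1e-8) {
  expect_equal(
    as.numeric(as.matrix(tibble::as_tibble(actual)[behavior_cols()])),
    as.numeric(expected),
    tolerance = tol
  )
}
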