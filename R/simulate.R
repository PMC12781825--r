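# Synthetic cohorts with the statistical structure the estimators assume:
# logistic-normal 24-hour compositions conditional on covariates,
# discrete-time dementia and death hazards (death drawn before dementia
# within an interval), administrative censoring near 8 years, optional MRI
# outcomes linear in the ILR coordinates, and covariate missingness. All
# parameters are held in a `truth_params` object so recovery tests and the
# Monte-Carlo risk oracle can be run against known ground truth.

# Log-scale covariance of the four behaviour parts implied by the cohort's
# geometric standard deviations, with mild correlations (more inactivity
# trades off against activity), projected into ILR space.
default_ilr_cov <- function() {
  gsd <- c(sleep = 1.2, inactivity = 1.1, light = 1.3, mvpa = 1.5)
  s <- log(gsd)
  R <- diag(4)
  dimnames(R) <- list(names(gsd), names(gsd))
  R["sleep", "inactivity"] <- R["inactivity", "sleep"] <- -0.2
  R["inactivity", "light"] <- R["light", "inactivity"] <- -0.4
  R["inactivity", "mvpa"] <- R["mvpa", "inactivity"] <- -0.3
  R["light", "mvpa"] <- R["mvpa", "light"] <- 0.2
  S <- diag(s) %*% R %*% diag(s)
  V <- ilr_contrast_matrix()
  V %*% S %*% t(V)
}

#' Ground-truth parameters for synthetic cohorts
#'
#' Collects every parameter of the data-generating process: the ILR mean
#' and covariance of the logistic-normal compositions, covariate shifts of
#' the ILR mean, coefficient lists for the discrete-time dementia and death
#' hazards (on the logit scale), follow-up structure, MRI outcome models,
#' and covariate missingness. Defaults emulate the cohort the analysis
#' targets: compositional centre near 6.5 h sleep / 12 h inactivity /
#' 3.3 h light / 1.7 h MVPA, ~1% cumulative dementia incidence over about
#' eight years of follow-up, and < 2% missingness in education and income.
#'
#' Hazard coefficient lists have elements `intercept`, `k_slope` (per
#' interval), `age` (per SD of age), `apoe4` (per allele), `female`, `z`
#' (length 3, on the ILR coordinates), `z_k` (length 3, ILR x interval
#' products), `short_sleep` (per hour of sleep below 6 h, a curvature
#' term that makes very short sleep harmful), and `log_mvpa` (per log
#' minute of MVPA, for strictly MVPA-monotone scenarios). ILR coordinates
#' and the log-MVPA term are centred at the truth's compositional centre,
#' so `intercept` is the logit hazard there.
#'
#' @param ilr_mean Length-3 ILR mean; default is the ILR image of the
#'   target geometric-mean composition.
#' @param ilr_cov 3x3 positive-definite ILR covariance.
#' @param covariate_ilr List with `age_sd` and `female` length-3 shifts of
#'   the ILR mean.
#' @param dem,death Hazard coefficient lists (see Details).
#' @param K Number of yearly intervals.
#' @param interval_days Interval length in days.
#' @param censor_years_range Administrative censoring drawn uniformly over
#'   this range (years), giving person-level follow-up of `K - 1` or `K`
#'   intervals.
#' @param mri MRI outcome settings: `imaging_fraction`, residual `sd`, and
#'   per-outcome coefficient lists.
#' @param missing Named missingness rates and mechanism (`"MCAR"` or
#'   `"MAR"`).
#' @return Object of class `truth_params`.
#' @export
truth_params <- function(
    ilr_mean = as.numeric(ilr_transform(close_composition(c(390, 720, 198, 102)))),
    ilr_cov = default_ilr_cov(),
    covariate_ilr = list(
      age_sd = c(0.03, 0.10, 0.08),
      female = c(0.02, -0.05, 0.10)
    ),
    dem = list(
      intercept = -8.8, k_slope = 0.20, age = 1.20, apoe4 = 0.80,
      female = 0, z = c(0, 0, 0), z_k = c(0, 0, 0), short_sleep = 0
    ),
    death = list(
      intercept = -5.6, k_slope = 0.08, age = 0.90, apoe4 = 0.10,
      female = -0.30, z = c(0, 0, 0), z_k = c(0, 0, 0), short_sleep = 0
    ),
    K = 9,
    interval_days = 365.25,
    censor_years_range = c(7.3, 9.0),
    mri = list(
      imaging_fraction = 0.17,
      outcomes = list(
        hippocampus_cm3 = list(
          intercept = 7.8, z = c(-0.10, -0.30, -0.20), age = -0.25,
          female = -0.10, center = c(0, 0.03, -0.02), motion = -0.3,
          head_position = 0.02, sd = 0.75
        ),
        log_wmh = list(
          intercept = 1.2, z = c(0.05, 0.20, 0.12), age = 0.45,
          female = -0.05, center = c(0, -0.02, 0.02), motion = 0.4,
          head_position = -0.01, sd = 0.70
        )
      )
    ),
    missing = list(
      rates = c(education = 0.02, income = 0.02),
      mechanism = "MCAR"
    )) {
  ev <- eigen(ilr_cov, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) abort("`ilr_cov` must be symmetric positive-definite")
  if (K < 2) abort("`K` must be at least 2")
  hazard_defaults <- list(
    intercept = -Inf, k_slope = 0, age = 0, apoe4 = 0, female = 0,
    z = c(0, 0, 0), z_k = c(0, 0, 0), short_sleep = 0, log_mvpa = 0
  )
  structure(
    list(
      ilr_mean = ilr_mean, ilr_cov = ilr_cov, covariate_ilr = covariate_ilr,
      dem = modifyList(hazard_defaults, dem),
      death = modifyList(hazard_defaults, death),
      K = K, interval_days = interval_days,
      censor_years_range = censor_years_range,
      mri = mri, missing = missing
    ),
    class = "truth_params"
  )
}

#' Truth presets
#'
#' Ready-made `truth_params` for the package's simulation studies:
#'
#' * `truth_default()` — cohort-realistic scales (~1% cumulative dementia
#'   incidence): protective MVPA direction plus a short-sleep curvature
#'   term, reproducing the qualitative substitution pattern.
#' * `truth_null()` — no composition effect on either hazard, with an
#'   elevated baseline dementia hazard so that null-calibration studies at
#'   a few thousand persons are dominated by bias rather than event
#'   sparsity (see the methods vignette for the power calculation).
#' * `truth_protective_mvpa()` — hazard exactly linear in the ILR
#'   coordinates with a protective MVPA direction and an elevated baseline;
#'   the well-specified recovery scenario.
#' * `truth_pattern()` — protective MVPA plus harmful very-short sleep at
#'   elevated baseline; the qualitative-pattern scenario.
#' * `truth_mvpa_gradient()` — dementia hazard strictly decreasing in
#'   MVPA minutes (`-gamma * log mvpa`, centred), independent of how the
#'   rest of the day is arranged; used by the composition-search tests.
#'
#' @param dem_intercept,dem_k_slope Baseline logit hazard and its linear
#'   trend per interval.
#' @param z Length-3 ILR coefficient vector of the dementia hazard.
#' @param short_sleep Logit increase per hour of sleep below 6 h.
#' @param gamma Strength of the MVPA log-contrast gradient.
#' @return A `truth_params` object.
#' @export
truth_default <- function() {
  truth_params(
    dem = list(
      intercept = -8.8, k_slope = 0.20, age = 1.20, apoe4 = 0.80,
      z = c(0.30, 0.20, 0.25), short_sleep = 0.30
    )
  )
}

#' @rdname truth_default
#' @export
truth_null <- function(dem_intercept = -2.3, dem_k_slope = 0.03) {
  truth_params(
    dem = list(
      intercept = dem_intercept, k_slope = dem_k_slope,
      age = 0.20, apoe4 = 0.20, z = c(0, 0, 0), short_sleep = 0
    ),
    death = list(intercept = -6.0, age = 0.3)
  )
}

#' @rdname truth_default
#' @export
truth_protective_mvpa <- function(dem_intercept = -3.4,
                                  z = c(0.30, 0.20, 0.25)) {
  truth_params(
    dem = list(
      intercept = dem_intercept, k_slope = 0.03, age = 0.30, apoe4 = 0.30,
      z = z, short_sleep = 0
    ),
    death = list(intercept = -6.0, age = 0.3)
  )
}

#' @rdname truth_default
#' @export
truth_pattern <- function(dem_intercept = -3.2, short_sleep = 0.5) {
  truth_params(
    dem = list(
      intercept = dem_intercept, k_slope = 0.03, age = 0.30, apoe4 = 0.30,
      z = c(0.30, 0.20, 0.25), short_sleep = short_sleep
    ),
    death = list(intercept = -6.0, age = 0.3)
  )
}

#' @rdname truth_default
#' @export
truth_mvpa_gradient <- function(gamma = 2, dem_intercept = -3.4) {
  truth_params(
    dem = list(
      intercept = dem_intercept, k_slope = 0.03, age = 0.30, apoe4 = 0.30,
      z = c(0, 0, 0), short_sleep = 0, log_mvpa = -gamma
    ),
    death = list(intercept = -6.0, age = 0.3)
  )
}

#' @export
print.truth_params <- function(x, ...) {
  cat("<truth_params> K =", x$K, "intervals of", x$interval_days, "days\n")
  cat("  ilr mean:", paste(round(x$ilr_mean, 3), collapse = ", "), "\n")
  cat("  dementia z coef:", paste(round(x$dem$z, 3), collapse = ", "),
      " short-sleep:", x$dem$short_sleep, "\n")
  invisible(x)
}

#' Generate baseline covariates
#'
#' Draws a covariate table with marginals loosely matched to a UK
#' community cohort in its seventh decade: age (median ~62, women 56%),
#' education and household-income bands, ethnicity, APOE e4 allele count,
#' and binary lifestyle covariates.
#'
#' @param n Number of persons (>= 1).
#' @param seed Integer seed; draws are reproducible given the seed.
#' @return Tibble with one row per person (`pid` = 1..n).
#' @export
generate_covariates <- function(n, seed = 1) {
  if (!is.numeric(n) || n < 1) abort("`n` must be at least 1")
  n <- as.integer(n)
  withr::with_seed(seed, {
    age <- pmin(pmax(rnorm(n, 61.5, 8), 44), 79)
    tibble(
      pid = seq_len(n),
      age = age,
      female = rbinom(n, 1, 0.56),
      education = sample(c("none", "secondary", "trade", "degree", "other"),
        n, replace = TRUE, prob = c(0.15, 0.062, 0.12, 0.59, 0.083)
      ),
      ethnicity = sample(c("white", "asian", "other"),
        n, replace = TRUE, prob = c(0.92, 0.039, 0.041)
      ),
      apoe4 = sample(0:2, n, replace = TRUE, prob = c(0.72, 0.26, 0.022)),
      income = sample(c("lt18", "18to30", "31to50", "52to100", "gt100"),
        n, replace = TRUE, prob = c(0.13, 0.22, 0.26, 0.23, 0.066)
      ),
      alcohol_daily = rbinom(n, 1, 0.23),
      fruit_veg = rbinom(n, 1, 0.40),
      antidepressant = rbinom(n, 1, 0.057),
      retired = rbinom(n, 1, 0.31),
      shift_work = rbinom(n, 1, 0.044)
    )
  })
}

# Standardized age used throughout the truth hazard functions.
age_sd_units <- function(age) (age - 62) / 8

#' Generate 24-hour compositions
#'
#' Draws ILR coordinates from a normal distribution whose mean shifts with
#' age and sex, then maps them to the simplex; all parts are positive by
#' construction.
#'
#' @param covariates Covariate table from [generate_covariates()].
#' @param truth A [truth_params()] object.
#' @param seed Integer seed.
#' @return Tibble with the four behaviour columns (closed to 1440).
#' @export
generate_compositions <- function(covariates, truth = truth_default(), seed = 1) {
  stopifnot(inherits(truth, "truth_params"))
  n <- nrow(covariates)
  mu <- matrix(truth$ilr_mean, n, 3, byrow = TRUE) +
    outer(age_sd_units(covariates$age), truth$covariate_ilr$age_sd) +
    outer(as.numeric(covariates$female), truth$covariate_ilr$female)
  L <- chol(truth$ilr_cov)
  z <- withr::with_seed(seed, {
    mu + matrix(rnorm(n * 3), n, 3) %*% L
  })
  colnames(z) <- paste0("z", 1:3)
  as_tibble(as.data.frame(ilr_inverse(z)))
}

# Truth hazard matrices (n x K) for a cohort table holding z1..z3,
# sleep_min, age, female, apoe4. ILR coordinates are centred at the
# truth's ILR mean, so `intercept` is the logit hazard at the
# compositional centre for a 62-year-old male APOE-e4 non-carrier.
truth_hazard_matrix <- function(cohort, coefs, K, ilr_mean) {
  n <- nrow(cohort)
  z <- as.matrix(cohort[paste0("z", 1:3)])
  z <- sweep(z, 2, ilr_mean)
  center <- ilr_inverse(ilr_mean)
  base <- coefs$intercept +
    coefs$age * age_sd_units(cohort$age) +
    coefs$apoe4 * cohort$apoe4 +
    coefs$female * cohort$female +
    as.numeric(z %*% coefs$z) +
    coefs$short_sleep * pmax(0, 360 - cohort$sleep_min) / 60 +
    coefs$log_mvpa * (log(cohort$mvpa_min) - log(center[["mvpa_min"]]))
  zk <- as.numeric(z %*% coefs$z_k)
  kk <- matrix(seq_len(K) - 1, n, K, byrow = TRUE)
  plogis(base + (coefs$k_slope + zk) * kk)
}

#' Generate dementia and death events
#'
#' For intervals `k = 1..K`, draws death with the death hazard and then,
#' if the person is still alive, dementia with the dementia hazard;
#' records the first event, with administrative censoring at a uniform
#' time inside `censor_years_range`. The per-interval true hazards and the
#' uncensored event history are retained in the `"hidden"` attribute for
#' recovery tests.
#'
#' @param cohort Covariates plus behaviour columns (one row per person).
#' @inheritParams generate_compositions
#' @return The cohort tibble with event columns `event_dem`, `time_dem`,
#'   `event_death`, `time_death`, `time_censor` (days), plus `status` and
#'   `time`; attribute `"hidden"` holds the truth.
#' @export
generate_events <- function(cohort, truth = truth_default(), seed = 1) {
  stopifnot(inherits(truth, "truth_params"))
  cohort <- add_ilr(as_tibble(cohort))
  n <- nrow(cohort)
  K <- truth$K
  hY <- truth_hazard_matrix(cohort, truth$dem, K, truth$ilr_mean)
  hD <- truth_hazard_matrix(cohort, truth$death, K, truth$ilr_mean)
  if (any(hY <= 0 & truth$dem$intercept > -Inf) || any(hY >= 1) || any(hD >= 1)) {
    abort("configured hazards fall outside (0, 1) on the generated support")
  }
  withr::with_seed(seed, {
    uD <- matrix(runif(n * K), n, K)
    uY <- matrix(runif(n * K), n, K)
    censor_days <- runif(n, truth$censor_years_range[1], truth$censor_years_range[2]) * 365.25
  })
  first_hit <- function(u, h) {
    hit <- u < h
    k <- rep(Inf, nrow(hit))
    for (j in rev(seq_len(ncol(hit)))) k[hit[, j]] <- j
    k
  }
  cand_death <- first_hit(uD, hD)
  cand_dem <- first_hit(uY, hY)
  # death drawn first within an interval: ties go to death
  event_k <- pmin(cand_death, cand_dem)
  type <- ifelse(is.infinite(event_k), "censored",
    ifelse(cand_death <= cand_dem, "death", "dementia")
  )
  censor_k <- pmin(K, ceiling(censor_days / truth$interval_days))
  censored <- is.infinite(event_k) | event_k > censor_k
  status <- ifelse(censored, "censored", type)
  event_time <- (event_k - 0.5) * truth$interval_days
  out <- cohort
  out$event_dem <- as.integer(status == "dementia")
  out$time_dem <- ifelse(status == "dementia", event_time, NA_real_)
  out$event_death <- as.integer(status == "death")
  out$time_death <- ifelse(status == "death", event_time, NA_real_)
  out$time_censor <- censor_days
  out$status <- status
  out$time <- ifelse(censored, censor_days, event_time)
  attr(out, "hidden") <- list(
    h_dem = hY, h_death = hD,
    cand_dem = cand_dem, cand_death = cand_death,
    censor_k = censor_k, status = status
  )
  out
}

#' Generate MRI volumetric outcomes
#'
#' Marks an imaging-substudy subset and, within it, draws each configured
#' outcome as a linear function of the ILR coordinates, age, sex, and
#' synthetic imaging covariates (assessment centre, head motion, head
#' position) plus Gaussian noise. Outcomes are NA outside the substudy.
#'
#' @inheritParams generate_events
#' @return Cohort tibble with `imaging`, `mri_center`, `head_motion`,
#'   `head_position`, and one column per configured outcome.
#' @export
generate_mri <- function(cohort, truth = truth_default(), seed = 1) {
  stopifnot(inherits(truth, "truth_params"))
  cohort <- add_ilr(as_tibble(cohort))
  n <- nrow(cohort)
  for (o in truth$mri$outcomes) {
    if (o$sd < 0) abort("MRI noise SD must be nonnegative")
  }
  withr::with_seed(seed, {
    imaging <- rbinom(n, 1, truth$mri$imaging_fraction) == 1
    center <- sample(c("A", "B", "C"), n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
    motion <- exp(rnorm(n, log(0.15), 0.3))
    headpos <- rnorm(n)
    out <- cohort
    out$imaging <- imaging
    out$mri_center <- center
    out$head_motion <- motion
    out$head_position <- headpos
    z <- as.matrix(cohort[paste0("z", 1:3)])
    center_idx <- match(center, c("A", "B", "C"))
    for (nm in names(truth$mri$outcomes)) {
      cf <- truth$mri$outcomes[[nm]]
      lp <- cf$intercept + as.numeric(z %*% cf$z) +
        cf$age * age_sd_units(cohort$age) + cf$female * cohort$female +
        cf$center[center_idx] + cf$motion * motion + cf$head_position * headpos
      y <- lp + rnorm(n, 0, cf$sd)
      y[!imaging] <- NA_real_
      out[[nm]] <- y
    }
  })
  out
}

#' Inject covariate missingness
#'
#' Masks covariate values at the configured rates, either completely at
#' random (MCAR) or at random given observed age and sex (MAR: masking
#' log-odds increase with age and differ by sex, rescaled to hit the
#' target marginal rate). Exposures and outcomes are never masked.
#'
#' @param cohort Cohort tibble.
#' @param rates Named vector of missingness rates in `[0, 0.5]` for
#'   covariate columns.
#' @param mechanism `"MCAR"` or `"MAR"`.
#' @param seed Integer seed.
#' @return Cohort tibble with NAs injected.
#' @export
inject_missingness <- function(cohort,
                               rates = c(education = 0.02, income = 0.02),
                               mechanism = c("MCAR", "MAR"), seed = 1) {
  mechanism <- arg_match(mechanism)
  if (any(rates < 0 | rates > 0.5)) abort("missingness rates must lie in [0, 0.5]")
  protected <- c(behavior_cols(), paste0("z", 1:3), "pid",
                 "event_dem", "time_dem", "event_death", "time_death",
                 "time_censor", "status", "time")
  if (any(names(rates) %in% protected)) {
    abort("exposures and outcomes are never masked")
  }
  missing_cols <- setdiff(names(rates), names(cohort))
  if (length(missing_cols) > 0) {
    abort(paste0("columns to mask not in cohort: ", paste(missing_cols, collapse = ", ")))
  }
  out <- as_tibble(cohort)
  n <- nrow(out)
  withr::with_seed(seed, {
    for (v in names(rates)) {
      r <- rates[[v]]
      if (r == 0) next
      if (mechanism == "MCAR") {
        p <- rep(r, n)
      } else {
        eta <- 0.8 * age_sd_units(out$age) + 0.3 * out$female
        # intercept solved so the marginal masking rate hits the target
        f <- function(a) mean(plogis(a + eta)) - r
        a <- stats::uniroot(f, c(-20, 5))$root
        p <- plogis(a + eta)
      }
      mask <- runif(n) < p
      out[[v]][mask] <- NA
    }
  })
  out
}

#' Simulate a complete cohort
#'
#' Convenience wrapper: covariates, compositions, events, MRI outcomes,
#' and (optionally) covariate missingness, all driven by a single seed.
#'
#' @param n Cohort size.
#' @param truth A [truth_params()] object.
#' @param seed Integer seed.
#' @param missingness Inject the truth's configured covariate missingness.
#' @param mri Generate MRI columns.
#' @return Cohort tibble (see the component generators); hidden truth in
#'   the `"hidden"` attribute.
#' @export
simulate_cohort <- function(n, truth = truth_default(), seed = 1,
                            missingness = FALSE, mri = FALSE) {
  covs <- generate_covariates(n, seed = seed)
  comp <- generate_compositions(covs, truth, seed = seed + 1L)
  cohort <- add_ilr(bind_cols(covs, comp))
  cohort <- generate_events(cohort, truth, seed = seed + 2L)
  hidden <- attr(cohort, "hidden")
  if (mri) cohort <- generate_mri(cohort, truth, seed = seed + 3L)
  if (missingness) {
    cohort <- inject_missingness(cohort,
      rates = truth$missing$rates,
      mechanism = truth$missing$mechanism, seed = seed + 4L
    )
  }
  attr(cohort, "hidden") <- hidden
  attr(cohort, "truth") <- truth
  cohort
}

#' Monte-Carlo oracle for true cumulative dementia incidence
#'
#' Averages the closed-form discrete-time cumulative incidence
#' `sum_k hY(k) (1 - hD(k)) prod_{j<k} (1 - hY(j))(1 - hD(j))` over fresh
#' covariate and composition draws from the truth, with a regime applied —
#' the ground truth against which g-formula estimates are compared.
#'
#' @param truth A [truth_params()] object.
#' @param regime A regime from [regime_observed()] and friends.
#' @param n_mc Number of Monte-Carlo draws (>= 1e4 recommended).
#' @param seed Integer seed. Using the same seed for two regimes evaluates
#'   them on the same draws, which is how oracle risk ratios should be
#'   computed.
#' @param subgroup Restrict to a sleep subgroup (by the drawn observed
#'   composition) before applying the regime.
#' @param K Number of intervals; defaults to the truth's.
#' @return Tibble with `risk`, `se` (Monte-Carlo standard error), and `n`.
#' @export
oracle_true_risk <- function(truth, regime = regime_observed(), n_mc = 1e5,
                             seed = 1, subgroup = "all", K = NULL) {
  stopifnot(inherits(truth, "truth_params"))
  if (is.null(K)) K <- truth$K
  covs <- generate_covariates(n_mc, seed = seed)
  comp <- generate_compositions(covs, truth, seed = seed + 1L)
  cohort <- add_ilr(bind_cols(covs, comp))
  cohort <- cohort[subgroup_members(cohort, subgroup), , drop = FALSE]
  reg <- apply_regime(cohort, regime)
  kept <- reg[reg$.keep, , drop = FALSE]
  hY <- truth_hazard_matrix(kept, truth$dem, K, truth$ilr_mean)
  hD <- truth_hazard_matrix(kept, truth$death, K, truth$ilr_mean)
  Fi <- cuminc_from_hazards(hY, hD)[, K]
  tibble(risk = mean(Fi), se = sd(Fi) / sqrt(length(Fi)), n = length(Fi))
}

#' @rdname oracle_true_risk
#' @param regime_num,regime_den Regimes for the numerator and denominator
#'   risks, evaluated on the same Monte-Carlo draws.
#' @return For `oracle_true_rr()`, the true risk ratio.
#' @export
oracle_true_rr <- function(truth, regime_num, regime_den = regime_observed(),
                           n_mc = 1e5, seed = 1, subgroup = "all", K = NULL) {
  num <- oracle_true_risk(truth, regime_num, n_mc, seed, subgroup, K)
  den <- oracle_true_risk(truth, regime_den, n_mc, seed, subgroup, K)
  num$risk / den$risk
}

#' Serialize truth parameters to YAML
#'
#' Writes every field of a [truth_params()] object to YAML (matrices as
#' row lists) and reads it back, so a simulation's ground truth can be
#' archived next to its outputs and reproduced exactly.
#'
#' @param truth A `truth_params` object.
#' @param path File path.
#' @return `write_truth_yaml()` returns `path` invisibly;
#'   `read_truth_yaml()` returns a `truth_params` object.
#' @export
write_truth_yaml <- function(truth, path) {
  stopifnot(inherits(truth, "truth_params"))
  x <- unclass(truth)
  x$ilr_cov <- apply(x$ilr_cov, 1, as.numeric, simplify = FALSE)
  x$missing$rates <- as.list(x$missing$rates)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_truth_yaml
#' @export
read_truth_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  x$ilr_cov <- do.call(rbind, lapply(x$ilr_cov, as.numeric))
  x$ilr_mean <- as.numeric(x$ilr_mean)
  x$missing$rates <- unlist(x$missing$rates)
  for (h in c("dem", "death")) {
    x[[h]] <- lapply(x[[h]], function(v) if (is.list(v)) unlist(v) else v)
  }
  x$covariate_ilr <- lapply(x$covariate_ilr, as.numeric)
  do.call(truth_params, x)
}
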