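# Discrete-time survival machinery: person-period expansion and pooled
# logistic maximum-likelihood fits for the dementia and death hazards.
# Within an interval death is ordered before dementia: a person who dies in
# interval k cannot have a dementia event in k, and the dementia model's
# risk set for k excludes rows with death in k. This matches the synthetic
# generator and the competing-risk factorization used by the g-formula.

# Derive first-event status and time (days) from the cohort event columns.
first_event <- function(cohort) {
  need <- c("event_dem", "time_dem", "event_death", "time_death", "time_censor")
  missing <- setdiff(need, names(cohort))
  if (length(missing) > 0) {
    abort(paste0("cohort event columns missing: ", paste(missing, collapse = ", ")))
  }
  t_dem <- ifelse(cohort$event_dem == 1, cohort$time_dem, Inf)
  t_death <- ifelse(cohort$event_death == 1, cohort$time_death, Inf)
  t_cens <- cohort$time_censor
  if (any(!is.finite(t_cens)) || any(t_cens < 0, na.rm = TRUE)) {
    abort("`time_censor` must be finite and nonnegative")
  }
  tt <- pmin(t_dem, t_death, t_cens)
  if (any(tt < 0)) abort("event times must be nonnegative")
  status <- ifelse(t_dem <= tt & is.finite(t_dem), "dementia",
    ifelse(t_death <= tt & is.finite(t_death), "death", "censored")
  )
  tibble(time = tt, status = status)
}

#' Expand a cohort into a person-period table
#'
#' One row per person per discrete time interval at risk. A person with
#' first event (or censoring) at time `t` contributes intervals
#' `k = 1..ceiling(t / interval_days)`; the interval-level `dementia` and
#' `death` indicators are 1 only in the final row of a person with that
#' first event.
#'
#' @param cohort Cohort data frame with the event columns `event_dem`,
#'   `time_dem`, `event_death`, `time_death`, `time_censor` (times in days
#'   from baseline), plus exposures/covariates to carry along. ILR
#'   coordinates are added from the behaviour columns if absent.
#' @param interval_days Interval length in days (default one year,
#'   365.25).
#' @param K Optional cap on the number of intervals (administrative
#'   truncation).
#' @return Tibble with columns `pid`, `k`, `dementia`, `death`, and all
#'   cohort columns.
#' @export
expand_person_periods <- function(cohort, interval_days = 365.25, K = NULL) {
  if (interval_days <= 0) abort("`interval_days` must be positive")
  fe <- first_event(cohort)
  k_last <- pmax(1L, as.integer(ceiling(fe$time / interval_days - 1e-9)))
  status <- fe$status
  if (!is.null(K)) {
    cap <- k_last > K
    status[cap] <- "censored"
    k_last[cap] <- K
  }
  cohort <- as_tibble(cohort)
  if (!all(c("z1", "z2", "z3") %in% names(cohort)) &&
    all(behavior_cols() %in% names(cohort))) {
    cohort <- add_ilr(cohort)
  }
  idx <- rep.int(seq_len(nrow(cohort)), k_last)
  out <- cohort[idx, , drop = FALSE]
  out$k <- sequence(k_last)
  last_row <- cumsum(k_last)
  out$dementia <- 0L
  out$death <- 0L
  out$dementia[last_row[status == "dementia"]] <- 1L
  out$death[last_row[status == "death"]] <- 1L
  out <- out |> select("pid", "k", "dementia", "death", dplyr::everything())
  out
}

#' Fit a pooled logistic hazard model
#'
#' Maximum-likelihood logistic regression on person-period rows,
#' approximating the discrete-time hazard. The death model uses all at-risk
#' rows; the dementia model excludes rows in which death occurred (death is
#' ordered first within an interval). The design must be full rank: rank
#' deficiency is a hard error naming the aliased columns, so bootstrap
#' replicates stay comparable (no silent dropping).
#'
#' @param pp Person-period table from [expand_person_periods()].
#' @param outcome `"dementia"` or `"death"`.
#' @param spec A [design_spec()]; resolved against the at-risk rows unless
#'   already resolved.
#' @param start Optional starting coefficients (warm start, used by the
#'   bootstrap).
#' @param check_rank Verify full column rank before fitting (a hard error
#'   naming aliased columns). May be disabled in bootstrap replicates of a
#'   design already validated on the full sample.
#' @param epsilon IRLS convergence tolerance on the relative deviance
#'   change.
#' @return An object of class `hazard_fit`: coefficients, convergence flag,
#'   log-likelihood, event count, and the frozen design spec.
#' @export
fit_pooled_logistic <- function(pp, outcome = c("dementia", "death"), spec,
                                start = NULL, check_rank = TRUE,
                                epsilon = 1e-10) {
  outcome <- arg_match(outcome)
  at_risk <- if (outcome == "dementia") pp$death == 0L else rep(TRUE, nrow(pp))
  data <- pp[at_risk, , drop = FALSE]
  y <- data[[outcome]]
  if (sum(y) == 0) abort(paste0("no ", outcome, " events among at-risk rows"))
  if (is.null(spec$knots)) spec <- resolve_design(spec, data)
  X <- build_design(data, spec)
  if (check_rank) {
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
      abort(paste0(
        "design is rank deficient; aliased columns: ",
        paste(aliased, collapse = ", ")
      ))
    }
  }
  fit <- fit_logistic_core(X, y, start = start, epsilon = epsilon)
  structure(
    list(
      outcome = outcome, coef = fit$coef, converged = fit$converged,
      loglik = fit$loglik, n = nrow(data), events = sum(y), spec = spec,
      interval_days = attr(pp, "interval_days")
    ),
    class = "hazard_fit"
  )
}

# Shared IRLS core: logistic maximum likelihood on a prebuilt design.
fit_logistic_core <- function(X, y, start = NULL, epsilon = 1e-10,
                              maxit = 100) {
  fit <- withCallingHandlers(
    stats::glm.fit(X, y,
      family = stats::binomial(),
      start = start,
      control = glm.control(epsilon = epsilon, maxit = maxit)
    ),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  mu <- fit$fitted.values
  list(
    coef = setNames(fit$coefficients, colnames(X)),
    converged = fit$converged,
    loglik = sum(y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300)))
  )
}

#' @export
print.hazard_fit <- function(x, ...) {
  cat("<hazard_fit> outcome:", x$outcome, "\n")
  cat("  person-periods:", x$n, " events:", x$events, "\n")
  cat("  terms:", length(x$coef), " logLik:", format(x$loglik), " converged:", x$converged, "\n")
  invisible(x)
}

#' Fit dementia and death hazard models
#'
#' Resolves the design against the person-period table once (shared knots
#' and factor levels) and fits the two pooled logistic models.
#'
#' @inheritParams fit_pooled_logistic
#' @param spec A [design_spec()].
#' @param start Optional `hazard_models` object whose coefficients warm-
#'   start the two fits (bootstrap replicates of the same design).
#' @return Object of class `hazard_models`: list with elements `dementia`
#'   and `death`.
#' @export
fit_hazard_models <- function(pp, spec = design_spec(), start = NULL,
                              check_rank = TRUE, epsilon = 1e-10) {
  if (is.null(spec$knots)) spec <- resolve_design(spec, pp)
  structure(
    list(
      dementia = fit_pooled_logistic(pp, "dementia", spec,
        start = start$dementia$coef, check_rank = check_rank, epsilon = epsilon
      ),
      death = fit_pooled_logistic(pp, "death", spec,
        start = start$death$coef, check_rank = check_rank, epsilon = epsilon
      )
    ),
    class = "hazard_models"
  )
}

#' @export
print.hazard_models <- function(x, ...) {
  print(x$dementia)
  print(x$death)
  invisible(x)
}

#' Predict a discrete-time hazard
#'
#' Inverse-logit of the linear predictor built with the fit's frozen design
#' spec. Values of splined variables beyond the boundary knots are handled
#' by the spline's linear tails; a single extrapolation warning is raised.
#'
#' @param fit A `hazard_fit`.
#' @param newdata Data frame with `k`, exposures, and covariates.
#' @param warn_extrapolation Emit a warning when splined variables fall
#'   outside their boundary knots.
#' @return Numeric vector of hazards in (0, 1).
#' @export
predict_hazard <- function(fit, newdata, warn_extrapolation = TRUE) {
  stopifnot(inherits(fit, "hazard_fit"))
  if (!isTRUE(fit$converged)) {
    warn("hazard fit did not converge; predictions may be unreliable")
  }
  if (warn_extrapolation) {
    for (v in names(fit$spec$knots)) {
      if (!v %in% names(newdata)) next
      kn <- fit$spec$knots[[v]]
      x <- newdata[[v]]
      if (any(x < kn[1] - 1e-12) || any(x > kn[length(kn)] + 1e-12)) {
        warn(paste0("`", v, "` outside boundary knots; linear-tail extrapolation used"))
        break
      }
    }
  }
  X <- build_design(newdata, fit$spec)
  as.numeric(plogis(X %*% fit$coef))
}

#' @export
tidy.hazard_fit <- function(x, ...) {
  tibble(term = names(x$coef), estimate = as.numeric(x$coef))
}

#' @export
glance.hazard_fit <- function(x, ...) {
  tibble(
    outcome = x$outcome, nobs = x$n, events = x$events,
    df = length(x$coef), logLik = x$loglik, converged = x$converged
  )
}
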