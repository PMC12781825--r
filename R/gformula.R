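# Parametric g-formula for cumulative dementia incidence under observed,
# substitution, and fixed-composition regimes, with death as a competing
# event. The estimand is the "total effect": the intervention changes the
# time-use composition (which may also shift the death hazard) but death is
# never eliminated. Per person
#   F_i(K) = sum_k hY_i(k) (1 - hD_i(k)) prod_{j<k} (1 - hY_i(j))(1 - hD_i(j))
# and the reported curve is the mean of F_i over the standardization
# population (a sleep subgroup or the full cohort).

#' Exposure regimes for the g-formula
#'
#' * `regime_observed()`: everyone keeps their observed composition
#'   ("natural course" reference).
#' * `regime_substitution()`: add `delta` minutes to `to` and subtract from
#'   `from`; a person for whom the substituted composition is infeasible
#'   (non-positive `from` part, or any part outside the sample range)
#'   either keeps the observed composition (`infeasible = "observed"`, the
#'   default) or is dropped from the standardization mean
#'   (`infeasible = "drop"`).
#' * `regime_fixed()`: everyone is assigned the same composition
#'   (covariates retained).
#'
#' @param from,to Behaviour names (see [behaviors()]).
#' @param delta Minutes reallocated (positive).
#' @param range Sample range tibble from [compute_sample_range()], or NULL
#'   to skip the range check (positivity only).
#' @param infeasible How individuals failing feasibility enter the
#'   standardization mean.
#' @param composition Length-4 composition (minutes, any form accepted by
#'   [close_composition()]).
#' @return A `regime` object.
#' @export
regime_observed <- function() {
  structure(list(type = "observed"), class = "regime")
}

#' @rdname regime_observed
#' @export
regime_substitution <- function(from, to, delta, range = NULL,
                                infeasible = c("observed", "drop")) {
  stopifnot(from %in% behaviors(), to %in% behaviors())
  if (from == to) abort("`from` and `to` must differ")
  if (!is.numeric(delta) || delta <= 0) abort("`delta` must be positive")
  structure(
    list(
      type = "substitution", from = from, to = to, delta = delta,
      range = range, infeasible = arg_match(infeasible)
    ),
    class = "regime"
  )
}

#' @rdname regime_observed
#' @export
regime_fixed <- function(composition) {
  comp <- close_composition(as_behavior_matrix(composition))
  structure(list(type = "fixed", composition = comp[1, ]), class = "regime")
}

#' @export
print.regime <- function(x, ...) {
  desc <- switch(x$type,
    observed = "observed (no intervention)",
    substitution = paste0(x$from, " -> ", x$to, ", ", x$delta, " min"),
    fixed = paste0("fixed composition (", paste(round(x$composition), collapse = "/"), " min)")
  )
  cat("<regime>", desc, "\n")
  invisible(x)
}

# Apply a regime to a cohort of persons. Returns the cohort with behaviour
# and z columns under the regime (in the given ILR basis), a logical
# `.feasible`, and a logical `.keep` (FALSE only under infeasible =
# "drop").
apply_regime <- function(cohort, regime, contrast = ilr_contrast_matrix()) {
  cohort <- as_tibble(cohort)
  if (regime$type == "observed") {
    out <- add_ilr(cohort, contrast = contrast)
    out$.feasible <- TRUE
    out$.keep <- TRUE
    return(out)
  }
  if (regime$type == "fixed") {
    out <- cohort
    out[behavior_cols()] <- as.data.frame(matrix(regime$composition,
      nrow = nrow(cohort), ncol = 4, byrow = TRUE,
      dimnames = list(NULL, behavior_cols())
    ))
    out <- add_ilr(out, contrast = contrast)
    out$.feasible <- TRUE
    out$.keep <- TRUE
    return(out)
  }
  sub <- apply_substitution(cohort, regime$from, regime$to, regime$delta)
  feas <- feasibility_mask(cohort, regime$from, regime$to, regime$delta,
    range = regime$range
  )
  out <- cohort
  for (col in behavior_cols()) {
    out[[col]] <- ifelse(feas, sub[[col]], cohort[[col]])
  }
  out <- add_ilr(out, contrast = contrast)
  out$.feasible <- feas
  out$.keep <- if (regime$infeasible == "drop") feas else TRUE
  out
}

# The ILR basis a fitted model's exposures live in.
fit_contrast <- function(fits) {
  fits$dementia$spec$contrast %||% ilr_contrast_matrix()
}

# Cumulative incidence from hazard matrices (n x K): death ordered before
# dementia within an interval.
cuminc_from_hazards <- function(hY, hD) {
  n <- nrow(hY)
  K <- ncol(hY)
  surv <- rep(1, n)
  Fmat <- matrix(0, n, K)
  acc <- rep(0, n)
  for (k in seq_len(K)) {
    acc <- acc + surv * (1 - hD[, k]) * hY[, k]
    Fmat[, k] <- acc
    surv <- surv * (1 - hD[, k]) * (1 - hY[, k])
  }
  Fmat
}

#' G-formula cumulative dementia incidence under a regime
#'
#' Standardizes model-based cumulative incidence over the covariate (and
#' observed-composition) distribution of a cohort subset: each person's
#' hazards are predicted at every interval `1..K` with their composition
#' set by the regime, combined into a per-person cumulative incidence with
#' death as a competing event, and averaged.
#'
#' @param cohort One row per person (behaviour columns + covariates). Pass
#'   a subgroup subset to standardize over that subgroup.
#' @param fits A `hazard_models` object from [fit_hazard_models()].
#' @param regime A regime from [regime_observed()] and friends.
#' @param K Number of intervals; must not exceed the fitted time range
#'   when the time basis is categorical.
#' @param warn_extrapolation Passed to [predict_hazard()].
#' @param weights Optional nonnegative person weights for the
#'   standardization mean — a post-stratification hook (e.g. weights that
#'   standardize a selected cohort to a reference population). Default is
#'   the unweighted mean.
#' @return A `risk_curve` tibble with columns `k` and `risk` (monotone
#'   nondecreasing), and attributes `n`, `feasible_fraction`, `regime`.
#' @export
estimate_risk <- function(cohort, fits, regime = regime_observed(), K,
                          warn_extrapolation = FALSE, weights = NULL) {
  stopifnot(inherits(fits, "hazard_models"))
  if (nrow(cohort) == 0) abort("empty standardization cohort")
  if (fits$dementia$spec$time_type == "factor" &&
    K > max(fits$dementia$spec$k_levels)) {
    abort("`K` exceeds the fitted time range of a categorical time basis")
  }
  if (!is.null(weights)) {
    if (length(weights) != nrow(cohort) || any(weights < 0) || all(weights == 0)) {
      abort("`weights` must be nonnegative, not all zero, one per person")
    }
  }
  reg <- apply_regime(cohort, regime, contrast = fit_contrast(fits))
  reg$.w <- weights %||% rep(1, nrow(reg))
  kept <- reg[reg$.keep, , drop = FALSE]
  if (nrow(kept) == 0) abort("no persons remain in the standardization mean")
  n <- nrow(kept)
  newdata <- kept[rep(seq_len(n), each = K), , drop = FALSE]
  newdata$k <- rep(seq_len(K), times = n)
  hY <- matrix(predict_hazard(fits$dementia, newdata, warn_extrapolation), n, K, byrow = TRUE)
  hD <- matrix(predict_hazard(fits$death, newdata, warn_extrapolation), n, K, byrow = TRUE)
  Fmat <- cuminc_from_hazards(hY, hD)
  w <- kept$.w / sum(kept$.w)
  curve <- tibble(k = seq_len(K), risk = as.numeric(crossprod(Fmat, w)))
  structure(curve,
    class = c("risk_curve", class(curve)),
    n = n,
    feasible_fraction = mean(reg$.feasible),
    regime = regime
  )
}

#' @rdname estimate_risk
#' @param x A `risk_curve`.
#' @export
feasible_fraction <- function(x) attr(x, "feasible_fraction")

#' Risk ratio between two risk curves
#'
#' Ratio of cumulative incidences at interval `at` (default end of
#' follow-up), numerator over denominator.
#'
#' @param numerator,denominator `risk_curve` objects over the same
#'   intervals.
#' @param at Interval at which to evaluate; defaults to the last.
#' @return A single numeric risk ratio.
#' @export
risk_ratio <- function(numerator, denominator, at = NULL) {
  if (nrow(numerator) != nrow(denominator)) {
    abort("risk curves must cover the same intervals")
  }
  if (is.null(at)) at <- max(numerator$k)
  fn <- numerator$risk[numerator$k == at]
  fd <- denominator$risk[denominator$k == at]
  if (length(fn) != 1 || length(fd) != 1) abort("`at` must match one interval")
  if (fd <= 0) abort("denominator risk is zero; risk ratio undefined")
  fn / fd
}

#' @export
autoplot.risk_curve <- function(object, ...) {
  df <- bind_rows(tibble(k = 0, risk = 0), as_tibble(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$risk)) +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = "Interval since baseline", y = "Cumulative dementia incidence"
    ) +
    ggplot2::theme_minimal()
}

# Per-row exposure-basis values for the z-dependent design columns of a
# fixed_composition_lp_parts() decomposition.
regime_sval_rows <- function(parts, zmat) {
  S <- matrix(0, nrow(zmat), length(parts$ids), dimnames = list(NULL, parts$ids))
  for (id in parts$ids) {
    coord <- sub("\\.[0-9]+$", "", id)
    basis <- as.integer(sub("^z[0-9]+\\.", "", id))
    zcol <- zmat[, coord]
    if (coord %in% names(parts$spec$knots)) {
      S[, id] <- rcs_basis(zcol, parts$spec$knots[[coord]])[, basis]
    } else {
      S[, id] <- zcol
    }
  }
  S
}

# Per-person end-of-follow-up risk under the observed regime and a list of
# further regimes, sharing one design decomposition: the exposure-free
# linear-predictor part and the multiplier matrix are built once, and each
# regime only contributes new exposure-basis values. Numerically identical
# to estimate_risk() per regime (same fits, same formula).
multi_regime_risk <- function(cohort, fits, regimes, K) {
  cohort <- add_ilr(as_tibble(cohort), contrast = fit_contrast(fits))
  n <- nrow(cohort)
  newdata <- cohort[rep(seq_len(n), each = K), , drop = FALSE]
  newdata$k <- rep(seq_len(K), times = n)
  pY <- fixed_composition_lp_parts(fits$dementia, newdata)
  pD <- fixed_composition_lp_parts(fits$death, newdata)
  all_regimes <- c(list(regime_observed()), regimes)
  Fi <- matrix(NA_real_, n, length(all_regimes))
  feas <- matrix(TRUE, n, length(all_regimes))
  keep <- matrix(TRUE, n, length(all_regimes))
  contrast <- fit_contrast(fits)
  for (j in seq_along(all_regimes)) {
    applied <- apply_regime(cohort, all_regimes[[j]], contrast = contrast)
    feas[, j] <- applied$.feasible
    keep[, j] <- applied$.keep
    zmat <- as.matrix(applied[paste0("z", 1:3)])[rep(seq_len(n), each = K), , drop = FALSE]
    colnames(zmat) <- paste0("z", 1:3)
    hY <- matrix(plogis(pY$A + rowSums(regime_sval_rows(pY, zmat) * pY$B)), n, K, byrow = TRUE)
    hD <- matrix(plogis(pD$A + rowSums(regime_sval_rows(pD, zmat) * pD$B)), n, K, byrow = TRUE)
    Fi[, j] <- cuminc_from_hazards(hY, hD)[, K]
  }
  list(Fi = Fi, feasible = feas, keep = keep)
}
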