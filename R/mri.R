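# Linear-model g-computation for continuous volumetric MRI outcomes:
# mean differences under isotemporal substitutions and predicted outcomes
# at selected fixed compositions. White-matter hyperintensity volume is
# analysed on the log scale; inputs are assumed already head-size
# normalized.

#' Fit a linear model for a volumetric MRI outcome
#'
#' Ordinary least squares on the imaging-substudy rows: the outcome is
#' regressed on the ILR coordinates (linear by default, restricted cubic
#' splines optionally), covariates, and the imaging covariates
#' (assessment centre, head motion, head position in the scanner). The
#' design must be full rank.
#'
#' @param cohort Cohort tibble including the outcome and an `imaging`
#'   flag (rows with NA outcome are dropped).
#' @param outcome Outcome column name.
#' @param covariates Covariate column names.
#' @param imaging_covariates Imaging covariate column names.
#' @param z_spline Use restricted cubic splines (4 knots) on the ILR
#'   coordinates instead of linear terms.
#' @return Object of class `outcome_fit` with coefficients, standard
#'   errors, residual SD, and the frozen design spec.
#' @export
fit_linear_outcome <- function(cohort, outcome,
                               covariates = c("age", "female", "apoe4"),
                               imaging_covariates = c("mri_center", "head_motion", "head_position"),
                               z_spline = FALSE) {
  cohort <- add_ilr(as_tibble(cohort))
  data <- cohort[!is.na(cohort[[outcome]]), , drop = FALSE]
  if (nrow(data) == 0) abort("no rows with an observed outcome")
  spec <- design_spec(
    covariates = c(covariates, imaging_covariates),
    key_covariates = character(0),
    spline_vars = if (z_spline) c("z1", "z2", "z3") else character(0),
    time_type = "none",
    exposure_time = FALSE, exposure_key = FALSE, key_time = FALSE
  )
  spec <- resolve_design(spec, data)
  X <- build_design(data, spec)
  if (nrow(X) < 10 * ncol(X)) {
    warn("fewer than 10 rows per design column; outcome fit may be unstable")
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0("outcome design is rank deficient; aliased columns: ", paste(aliased, collapse = ", ")))
  }
  fit <- stats::lm.fit(X, data[[outcome]])
  res <- fit$residuals
  dfres <- nrow(X) - ncol(X)
  sigma <- sqrt(sum(res^2) / dfres)
  XtX_inv <- chol2inv(qr.R(qrX))
  se <- sigma * sqrt(diag(XtX_inv))
  structure(
    list(
      outcome = outcome, coef = setNames(fit$coefficients, colnames(X)),
      se = setNames(se, colnames(X)), sigma = sigma, n = nrow(X),
      spec = spec
    ),
    class = "outcome_fit"
  )
}

#' @export
print.outcome_fit <- function(x, ...) {
  cat("<outcome_fit>", x$outcome, " n =", x$n, " residual SD =", signif(x$sigma, 4), "\n")
  invisible(x)
}

#' @export
tidy.outcome_fit <- function(x, ...) {
  est <- as.numeric(x$coef)
  se <- as.numeric(x$se)
  tibble(
    term = names(x$coef), estimate = est, std.error = se,
    statistic = est / se,
    p.value = 2 * stats::pt(-abs(est / se), df = x$n - length(est))
  )
}

#' @export
glance.outcome_fit <- function(x, ...) {
  tibble(outcome = x$outcome, nobs = x$n, sigma = x$sigma, df = length(x$coef))
}

# Predict the outcome for a cohort (uses the fit's frozen design).
predict_outcome <- function(fit, cohort) {
  data <- add_ilr(as_tibble(cohort))
  X <- build_design(data, fit$spec)
  as.numeric(X %*% fit$coef)
}

#' G-computation mean difference for an MRI outcome
#'
#' Mean over the (subgroup) cohort of the predicted outcome at the
#' substituted composition minus the predicted outcome at the observed
#' composition. Feasibility and the 75% presentation rule follow the
#' dementia substitution analyses: infeasible individuals keep their
#' observed composition (contributing zero difference).
#'
#' @param fit An [fit_linear_outcome()] result.
#' @param cohort Standardization cohort (e.g. an imaging subgroup).
#' @param from,to,delta Substitution definition.
#' @param range Sample range from [compute_sample_range()] (NULL for
#'   positivity-only feasibility).
#' @param presented_threshold Minimum feasible fraction for presentation.
#' @return One-row tibble: `outcome`, `from`, `to`, `delta`, `md`,
#'   `feasible_fraction`, `presented`.
#' @export
gcomp_mean_difference <- function(fit, cohort, from, to, delta, range = NULL,
                                  presented_threshold = 0.75) {
  stopifnot(inherits(fit, "outcome_fit"))
  cohort <- as_tibble(cohort)
  reg <- regime_substitution(from, to, delta, range = range, infeasible = "observed")
  sub <- apply_regime(cohort, reg)
  md <- mean(predict_outcome(fit, sub) - predict_outcome(fit, cohort))
  ff <- mean(sub$.feasible)
  tibble(
    outcome = fit$outcome, from = from, to = to, delta = delta,
    md = md, feasible_fraction = ff,
    presented = ff >= presented_threshold
  )
}

#' Predicted MRI outcomes at selected compositions
#'
#' Mean predicted outcome with every person in the cohort assigned each
#' fixed composition in turn (covariates retained) — used for the
#' lowest/typical/highest-risk compositions.
#'
#' @param fit An [fit_linear_outcome()] result.
#' @param cohort Standardization cohort.
#' @param compositions A data frame of compositions (e.g. the `test_risks`
#'   table of a [crossvalidated_selection()], or any rows with the four
#'   behaviour columns).
#' @return Tibble: one row per composition with the behaviour columns and
#'   `predicted`.
#' @export
predict_at_compositions <- function(fit, cohort, compositions) {
  comps <- as_tibble(compositions)
  out <- comps[intersect(c("which", behavior_cols()), names(comps))]
  out$predicted <- vapply(seq_len(nrow(comps)), function(i) {
    reg <- regime_fixed(as.numeric(comps[i, behavior_cols()]))
    sub <- apply_regime(cohort, reg)
    mean(predict_outcome(fit, sub))
  }, numeric(1))
  out
}
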