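# Missing-data and uncertainty machinery. Covariate missingness is
# imputed by predictive mean matching with chained equations; imputation
# uncertainty is propagated through the nonparametric bootstrap with one
# imputation per bootstrap sample, and confidence intervals are percentile
# intervals of the replicate estimates. The person is the resampling unit.

# Numeric design matrix of predictors for the imputation model of `target`:
# all other covariates (current completed values), exposures (ILR), and
# outcome variables.
impute_predictor_matrix <- function(data, target, predictors) {
  cols <- list(`(Intercept)` = rep(1, nrow(data)))
  for (v in setdiff(predictors, target)) {
    col <- data[[v]]
    if (is.character(col) || is.factor(col) || is.logical(col)) {
      f <- as.factor(col)
      for (l in levels(f)[-1]) cols[[paste0(v, l)]] <- as.numeric(f == l)
    } else {
      cols[[v]] <- as.numeric(col)
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  X
}

# Least-squares predictions that tolerate collinear predictors (rank-
# revealing QR; aliased directions get zero weight).
ls_predict <- function(X, y, Xnew) {
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  list(fitted = as.numeric(X %*% beta), new = as.numeric(Xnew %*% beta))
}

match_donors <- function(score_obs, score_mis, donors) {
  # score_*: numeric vectors or matrices (columns = score dimensions);
  # returns the k nearest observed rows per missing row (ties by index)
  so <- as.matrix(score_obs)
  sm <- as.matrix(score_mis)
  k <- min(donors, nrow(so))
  D2 <- outer(rowSums(sm^2), rowSums(so^2), "+") - 2 * tcrossprod(sm, so)
  idx <- matrix(0L, nrow(sm), k)
  for (j in seq_len(k)) {
    sel <- max.col(-D2, ties.method = "first")
    idx[, j] <- sel
    D2[cbind(seq_len(nrow(sm)), sel)] <- Inf
  }
  idx
}

#' Predictive-mean-matching imputation
#'
#' Chained-equation imputation of covariate missingness. Variables are
#' visited in order of ascending missingness for `cycles` rounds; each
#' missing cell is matched on the linear predictor of a least-squares
#' model (one-vs-rest scores for categorical targets) to its `donors`
#' nearest observed rows, and one donor's observed value is copied, so
#' imputed values always come from the observed support. Exposures and
#' outcome variables are used as predictors but never imputed.
#'
#' @param cohort Cohort tibble; missingness only in covariate columns.
#' @param donors Number of candidate donors per missing cell (k).
#' @param cycles Chained-equation cycles.
#' @param seed Integer seed (donor sampling and initial fill-in).
#' @param predictors Columns used in the imputation models; defaults to
#'   the ILR coordinates, event indicators, follow-up time, and every
#'   covariate column with or without missingness.
#' @param exclude Columns never imputed even when missing. Defaults to the
#'   structurally missing columns of the cohort schema: event times (NA
#'   without an event) and MRI outcomes (NA outside the imaging substudy).
#'   Add outcome columns here when the cohort carries others.
#' @return Completed cohort tibble (no NAs among the imputed columns).
#' @export
pmm_impute <- function(cohort, donors = 5, cycles = 5, seed = 1,
                       predictors = NULL,
                       exclude = c(
                         "time_dem", "time_death", "hippocampus_cm3",
                         "log_wmh"
                       )) {
  if (donors < 1) abort("`donors` must be at least 1")
  if (cycles < 1) abort("`cycles` must be at least 1")
  cohort <- as_tibble(cohort)
  n_miss <- vapply(cohort, function(c) sum(is.na(c)), integer(1))
  targets <- setdiff(names(n_miss)[n_miss > 0], exclude)
  if (length(targets) == 0) {
    return(cohort)
  }
  fully_missing <- targets[n_miss[targets] == nrow(cohort)]
  if (length(fully_missing) > 0) {
    abort(paste0("variable(s) 100% missing cannot be imputed: ", paste(fully_missing, collapse = ", ")))
  }
  protected <- c(behavior_cols(), paste0("z", 1:3))
  if (any(targets %in% protected)) {
    abort("missingness is only supported in covariate columns, not exposures")
  }
  if (is.null(predictors)) {
    auto <- c(
      paste0("z", 1:3), "event_dem", "event_death", "time",
      "age", "female", "education", "ethnicity", "apoe4", "income",
      "alcohol_daily", "fruit_veg", "antidepressant", "retired", "shift_work"
    )
    predictors <- intersect(unique(c(auto, targets)), names(cohort))
  }
  targets <- targets[order(n_miss[targets])]
  miss_idx <- lapply(cohort[targets], function(c) which(is.na(c)))
  names(miss_idx) <- targets

  withr::with_seed(seed, {
    data <- cohort
    # initial fill-in: random draws from the observed values
    for (v in targets) {
      obs <- which(!is.na(cohort[[v]]))
      mis <- miss_idx[[v]]
      data[[v]][mis] <- cohort[[v]][sample(obs, length(mis), replace = TRUE)]
    }
    for (cycle in seq_len(cycles)) {
      for (v in targets) {
        mis <- miss_idx[[v]]
        obs <- setdiff(seq_len(nrow(data)), mis)
        X <- impute_predictor_matrix(data, v, predictors)
        yv <- cohort[[v]]
        if (is.character(yv) || is.factor(yv) || is.logical(yv)) {
          f <- as.factor(yv)
          scores_obs <- matrix(0, length(obs), nlevels(f))
          scores_mis <- matrix(0, length(mis), nlevels(f))
          for (li in seq_len(nlevels(f))) {
            yb <- as.numeric(f[obs] == levels(f)[li])
            pr <- ls_predict(X[obs, , drop = FALSE], yb, X[mis, , drop = FALSE])
            scores_obs[, li] <- pr$fitted
            scores_mis[, li] <- pr$new
          }
          donor_idx <- match_donors(scores_obs, scores_mis, donors)
        } else {
          pr <- ls_predict(X[obs, , drop = FALSE], as.numeric(yv[obs]), X[mis, , drop = FALSE])
          donor_idx <- match_donors(pr$fitted, pr$new, donors)
        }
        pick <- donor_idx[cbind(
          seq_len(length(mis)),
          sample.int(ncol(donor_idx), length(mis), replace = TRUE)
        )]
        data[[v]][mis] <- yv[obs][pick]
      }
    }
    data
  })
}

#' Bootstrap a pipeline estimator
#'
#' Nonparametric bootstrap with the person as the resampling unit. For
#' each of `B` replicates the cohort rows are resampled with replacement,
#' optionally completed with a replicate-specific [pmm_impute()] (one
#' imputation per bootstrap sample), and passed to `estimator`, which must
#' return a named numeric vector of estimands. Confidence intervals are
#' percentile intervals over the finite replicate estimates; replicate
#' failures are logged and more than `max_failures` of them is an error.
#'
#' @param cohort Cohort tibble (one row per person).
#' @param estimator Function `cohort -> named numeric vector`.
#' @param B Number of bootstrap replicates (>= 2; >= 200 recommended).
#' @param seed Integer seed driving resampling and replicate imputations.
#' @param impute Run [pmm_impute()] inside each replicate (and once, with
#'   the master seed, for the point estimate).
#' @param donors,cycles,impute_exclude Imputation settings (see
#'   [pmm_impute()]).
#' @param level Confidence level.
#' @param max_failures Maximum tolerated fraction of failed replicates.
#' @return A `bootstrap_result` tibble: `estimand`, `estimate`,
#'   `conf.low`, `conf.high`, with attributes `replicates` (B x estimand
#'   matrix) and `n_failed`.
#' @export
bootstrap_pipeline <- function(cohort, estimator, B = 200, seed = 1,
                               impute = FALSE, donors = 5, cycles = 5,
                               impute_exclude = eval(formals(pmm_impute)$exclude),
                               level = 0.95, max_failures = 0.10) {
  if (B < 2) abort("`B` must be at least 2")
  if (B < 200) warn("fewer than 200 bootstrap replicates; intervals will be noisy")
  cohort <- as_tibble(cohort)
  n <- nrow(cohort)
  point_data <- if (impute) {
    pmm_impute(cohort, donors, cycles, seed = seed, exclude = impute_exclude)
  } else {
    cohort
  }
  point <- estimator(point_data)
  if (is.null(names(point))) names(point) <- paste0("estimand", seq_along(point))

  seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, 2L * B))
  reps <- matrix(NA_real_, B, length(point), dimnames = list(NULL, names(point)))
  failures <- character(0)
  for (b in seq_len(B)) {
    idx <- withr::with_seed(seeds[b], sample.int(n, n, replace = TRUE))
    boot <- cohort[idx, , drop = FALSE]
    boot$pid <- seq_len(n)
    res <- tryCatch(
      {
        if (impute) {
          boot <- pmm_impute(boot, donors, cycles,
            seed = seeds[B + b], exclude = impute_exclude
          )
        }
        estimator(boot)
      },
      error = function(e) conditionMessage(e)
    )
    if (is.character(res)) {
      failures <- c(failures, res)
    } else {
      reps[b, ] <- res
    }
  }
  if (length(failures) > max_failures * B) {
    abort(paste0(
      length(failures), "/", B, " bootstrap replicates failed; first error: ",
      failures[1]
    ))
  }
  alpha <- (1 - level) / 2
  ok <- stats::complete.cases(reps)
  ci <- apply(reps[ok, , drop = FALSE], 2, quantile,
    probs = c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE
  )
  out <- tibble(
    estimand = names(point),
    estimate = as.numeric(point),
    conf.low = unname(ci[1, ]),
    conf.high = unname(ci[2, ])
  )
  attr(out, "replicates") <- reps
  attr(out, "n_failed") <- length(failures)
  attr(out, "B") <- B
  class(out) <- c("bootstrap_result", class(out))
  out
}

#' @rdname bootstrap_pipeline
#' @param x A `bootstrap_result`.
#' @export
bootstrap_replicates <- function(x) attr(x, "replicates")

#' @export
tidy.bootstrap_result <- function(x, ...) as_tibble(x)

#' @export
glance.bootstrap_result <- function(x, ...) {
  tibble(B = attr(x, "B"), n_failed = attr(x, "n_failed"), n_estimands = nrow(x))
}

#' Fast bootstrap intervals for substitution risk ratios
#'
#' Percentile bootstrap tailored to the hazard-model substitution
#' analysis. The person-period design matrices (observed and under each
#' substitution regime) are built once on the full cohort with knots and
#' factor levels frozen, so each replicate only refits the two pooled
#' logistic models on resampled rows (warm-started at the full-sample
#' coefficients) and re-evaluates the g-formula risks — the estimand is
#' identical to [run_substitution_matrix()] with the same frozen design.
#' The person is the resampling unit; subgroup standardization populations
#' are resampled with the cohort.
#'
#' @param cohort Analysis cohort (one row per person, complete
#'   covariates).
#' @param spec A [design_spec()].
#' @param K Number of intervals.
#' @param regimes List of substitution regimes from
#'   [regime_substitution()] (a sample range should be embedded in each).
#' @param subgroups Subgroup labels to standardize over.
#' @param B Bootstrap replicates.
#' @param seed Integer seed.
#' @param interval_days Interval length.
#' @param level Confidence level.
#' @param epsilon IRLS tolerance for replicate refits.
#' @return Tibble: `subgroup`, `from`, `to`, `delta`, `rr`, `conf.low`,
#'   `conf.high`, `feasible_fraction`, `presented`; attribute
#'   `"replicates"` holds the B x estimand matrix.
#' @export
bootstrap_substitution_rr <- function(cohort, spec, K, regimes,
                                      subgroups = c("short", "normal", "long"),
                                      B = 200, seed = 1,
                                      interval_days = 365.25,
                                      level = 0.95, epsilon = 1e-8) {
  cohort <- as_tibble(cohort)
  n <- nrow(cohort)
  pp <- expand_person_periods(cohort, interval_days = interval_days, K = K)
  spec <- resolve_design(spec, pp)

  # full person-period design (death model rows); dementia model drops
  # death-in-interval rows
  X_all <- build_design(pp, spec)
  y_death <- pp$death
  y_dem <- pp$dementia
  dem_rows <- which(pp$death == 0L)

  # contiguous per-person row ranges in pp (cohort order)
  len_all <- as.integer(table(factor(pp$pid, levels = cohort$pid)))
  start_all <- c(0L, cumsum(len_all)[-n]) + 1L
  in_dem <- pp$death == 0L
  len_dem <- as.integer(rowsum(as.numeric(in_dem), factor(pp$pid, levels = cohort$pid)))
  # dem-row positions within dem_rows: persons stay contiguous
  start_dem <- c(0L, cumsum(len_dem)[-n]) + 1L
  X_dem <- X_all[dem_rows, , drop = FALSE]
  y_dem <- y_dem[dem_rows]

  # prediction designs over persons x K under each regime
  newdata <- cohort[rep(seq_len(n), each = K), , drop = FALSE]
  newdata$k <- rep(seq_len(K), times = n)
  contrast <- spec$contrast %||% ilr_contrast_matrix()
  pred_X <- list(observed = build_design(add_ilr(newdata, contrast = contrast), spec))
  feas <- list()
  for (i in seq_along(regimes)) {
    reg <- regimes[[i]]
    applied <- apply_regime(cohort, reg, contrast = contrast)
    feas[[i]] <- applied$.feasible
    nd <- applied[rep(seq_len(n), each = K), , drop = FALSE]
    nd$k <- rep(seq_len(K), times = n)
    pred_X[[i + 1]] <- build_design(nd, spec)
  }

  membership <- lapply(subgroups, function(sg) subgroup_members(cohort, sg))
  names(membership) <- subgroups

  risk_per_person <- function(coef_dem, coef_death, Xp) {
    hY <- matrix(plogis(Xp %*% coef_dem), n, K, byrow = TRUE)
    hD <- matrix(plogis(Xp %*% coef_death), n, K, byrow = TRUE)
    cuminc_from_hazards(hY, hD)[, K]
  }

  estimands <- character(0)
  for (sg in subgroups) {
    for (reg in regimes) {
      estimands <- c(estimands, paste(sg, reg$from, reg$to, reg$delta, sep = "."))
    }
  }

  compute_rrs <- function(coef_dem, coef_death, idx) {
    Fi <- lapply(pred_X, function(Xp) risk_per_person(coef_dem, coef_death, Xp))
    out <- numeric(0)
    for (sg in subgroups) {
      midx <- idx[membership[[sg]][idx]]
      f_obs <- mean(Fi[[1]][midx])
      for (i in seq_along(regimes)) {
        out <- c(out, mean(Fi[[i + 1]][midx]) / f_obs)
      }
    }
    setNames(out, estimands)
  }

  fit0_dem <- fit_logistic_core(X_dem, y_dem, epsilon = 1e-10)
  fit0_death <- fit_logistic_core(X_all, y_death, epsilon = 1e-10)
  point <- compute_rrs(fit0_dem$coef, fit0_death$coef, seq_len(n))

  seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, B))
  reps <- matrix(NA_real_, B, length(point), dimnames = list(NULL, names(point)))
  for (b in seq_len(B)) {
    idx <- withr::with_seed(seeds[b], sample.int(n, n, replace = TRUE))
    rows_all <- sequence(len_all[idx], from = start_all[idx])
    rows_dem <- sequence(len_dem[idx], from = start_dem[idx])
    fb_dem <- fit_logistic_core(X_dem[rows_dem, , drop = FALSE], y_dem[rows_dem],
      start = fit0_dem$coef, epsilon = epsilon
    )
    fb_death <- fit_logistic_core(X_all[rows_all, , drop = FALSE], y_death[rows_all],
      start = fit0_death$coef, epsilon = epsilon
    )
    reps[b, ] <- compute_rrs(fb_dem$coef, fb_death$coef, idx)
  }
  alpha <- (1 - level) / 2
  ci <- apply(reps, 2, quantile, probs = c(alpha, 1 - alpha), names = FALSE)

  meta <- tidyr::expand_grid(
    subgroup = subgroups,
    regime_i = seq_along(regimes)
  )
  out <- tibble(
    subgroup = meta$subgroup,
    from = vapply(regimes[meta$regime_i], function(r) r$from, ""),
    to = vapply(regimes[meta$regime_i], function(r) r$to, ""),
    delta = vapply(regimes[meta$regime_i], function(r) r$delta, 0),
    rr = as.numeric(point),
    conf.low = ci[1, ],
    conf.high = ci[2, ]
  )
  ff <- vapply(seq_len(nrow(meta)), function(j) {
    mean(feas[[meta$regime_i[j]]][membership[[meta$subgroup[j]]]])
  }, numeric(1))
  out$feasible_fraction <- ff
  out$presented <- ff >= 0.75
  attr(out, "replicates") <- reps
  attr(out, "B") <- B
  class(out) <- c("bootstrap_result", class(out))
  out
}
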