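# Flexible design construction for the pooled logistic hazard models:
# restricted cubic splines for continuous predictors, dummy coding for
# categoricals, and the product structure exposure x time, exposure x key
# covariates, key covariates x time. Product terms use the linear component
# of each factor so the interaction surface stays interpretable and the
# design desk-scale; spline main effects capture the marginal curvature.

#' Restricted cubic spline basis
#'
#' Harrell's truncated-power restricted cubic spline: for `m` knots returns
#' `m - 1` columns (the linear term plus `m - 2` nonlinear terms), linear
#' beyond the boundary knots, with continuous first and second derivatives
#' everywhere. Nonlinear terms are scaled by the squared knot span so the
#' columns are on a comparable scale to `x`.
#'
#' @param x Numeric vector.
#' @param knots Strictly increasing numeric vector of at least 3 knots.
#' @return Matrix with `length(knots) - 1` columns named `b1` (linear),
#'   `b2`, ...
#' @export
rcs_basis <- function(x, knots) {
  if (length(knots) < 3) abort("restricted cubic splines need at least 3 knots")
  if (is.unsorted(knots, strictly = TRUE)) abort("knots must be strictly increasing (no duplicates)")
  m <- length(knots)
  km1 <- knots[m - 1]
  km <- knots[m]
  scale2 <- (km - knots[1])^2
  pos3 <- function(u) pmax(u, 0)^3
  out <- matrix(0, length(x), m - 1)
  out[, 1] <- x
  for (j in seq_len(m - 2)) {
    out[, j + 1] <- (pos3(x - knots[j]) -
      pos3(x - km1) * (km - knots[j]) / (km - km1) +
      pos3(x - km) * (km1 - knots[j]) / (km - km1)) / scale2
  }
  colnames(out) <- paste0("b", seq_len(m - 1))
  out
}

# Default knot placement: quantiles of the fitting data at 5/35/65/95 for
# 4 knots (Harrell's convention); equally spaced tail probabilities for
# other counts. Degenerate (tied) knots collapse to a linear term.
default_knots <- function(x, n_knots = 4) {
  probs <- switch(as.character(n_knots),
    "3" = c(0.10, 0.50, 0.90),
    "4" = c(0.05, 0.35, 0.65, 0.95),
    "5" = c(0.05, 0.275, 0.50, 0.725, 0.95),
    seq(0.05, 0.95, length.out = n_knots)
  )
  k <- unique(quantile(x, probs, type = 7, names = FALSE))
  if (length(k) < 3) NULL else k
}

#' Specify a hazard-model design
#'
#' Describes the design matrix for the pooled logistic hazard models:
#' which covariates enter, which continuous variables get restricted cubic
#' splines, which covariates are "key" (interacted with the exposures and
#' with time), and which product blocks are included. Knot locations are
#' resolved from the fitting data by [fit_hazard_models()] and frozen into
#' the fit, so predictions use the same basis.
#'
#' @param covariates Character vector of covariate column names (numeric or
#'   categorical).
#' @param key_covariates Subset of `covariates` treated as key covariates
#'   for the product terms. Defaults to the intersection of
#'   `c("age", "female", "apoe4")` with `covariates`.
#' @param spline_vars Continuous variables receiving restricted cubic
#'   splines. Defaults to time (`"k"`), `"age"` if present, and the three
#'   ILR coordinates.
#' @param n_knots Number of knots per splined variable (default 4, placed
#'   at the 5/35/65/95 percentiles of the fitting data).
#' @param time_type `"rcs"`, `"linear"`, `"factor"` (one indicator per
#'   interval; used for saturated models), or `"none"` (no time axis:
#'   intercept-only baselines and cross-sectional outcome models).
#' @param exposure_time,exposure_key,key_time Logical switches for the
#'   three product blocks (linear-by-linear).
#' @param exposures Names of the exposure coordinates (default `z1..z3`).
#' @param contrast Orthonormal ILR contrast matrix defining the exposure
#'   coordinates (the sequential binary partition); regimes evaluated
#'   against a fit recompute coordinates in this basis. Any full-rank
#'   basis yields identical risks.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(covariates = character(),
                        key_covariates = intersect(c("age", "female", "apoe4"), covariates),
                        spline_vars = intersect(c("k", "age", "z1", "z2", "z3"),
                                                c("k", covariates, exposures)),
                        n_knots = 4,
                        time_type = c("rcs", "linear", "factor", "none"),
                        exposure_time = TRUE,
                        exposure_key = TRUE,
                        key_time = TRUE,
                        exposures = c("z1", "z2", "z3"),
                        contrast = ilr_contrast_matrix()) {
  time_type <- arg_match(time_type)
  if (!all(key_covariates %in% covariates)) {
    abort("`key_covariates` must be a subset of `covariates`")
  }
  if (time_type != "rcs") spline_vars <- setdiff(spline_vars, "k")
  structure(
    list(
      covariates = covariates, key_covariates = key_covariates,
      spline_vars = spline_vars, n_knots = n_knots, time_type = time_type,
      exposure_time = exposure_time, exposure_key = exposure_key,
      key_time = key_time, exposures = exposures, contrast = contrast,
      knots = NULL, levels = NULL, k_levels = NULL
    ),
    class = "design_spec"
  )
}

#' @export
print.design_spec <- function(x, ...) {
  cat("<design_spec>\n")
  cat("  covariates:", if (length(x$covariates)) paste(x$covariates, collapse = ", ") else "(none)", "\n")
  cat("  key covariates:", if (length(x$key_covariates)) paste(x$key_covariates, collapse = ", ") else "(none)", "\n")
  cat("  time:", x$time_type, " splines:", paste(x$spline_vars, collapse = ", "), "\n")
  cat("  products: exposure x time =", x$exposure_time,
      ", exposure x key =", x$exposure_key, ", key x time =", x$key_time, "\n")
  cat("  resolved:", !is.null(x$knots), "\n")
  invisible(x)
}

# Freeze knots and factor levels against the fitting data.
resolve_design <- function(spec, data) {
  stopifnot(inherits(spec, "design_spec"))
  need_k <- if (spec$time_type == "none") character(0) else "k"
  missing <- setdiff(c(spec$covariates, spec$exposures, need_k), names(data))
  if (length(missing) > 0) {
    abort(paste0("design references columns absent from the data: ", paste(missing, collapse = ", ")))
  }
  knots <- list()
  for (v in spec$spline_vars) {
    kn <- default_knots(data[[v]], spec$n_knots)
    if (!is.null(kn)) knots[[v]] <- kn
  }
  spec$knots <- knots
  levels <- list()
  for (v in spec$covariates) {
    col <- data[[v]]
    if (is.character(col) || is.factor(col) || is.logical(col)) {
      levels[[v]] <- levels(as.factor(col))
    }
  }
  spec$levels <- levels
  if (spec$time_type == "factor") spec$k_levels <- sort(unique(data$k))
  spec
}

# Linear/dummy columns of the key covariates (used both for product-term
# construction and for the fast fixed-composition risk path).
key_linear_columns <- function(data, spec) {
  out <- list()
  for (v in spec$key_covariates) {
    if (!is.null(spec$levels[[v]])) {
      lev <- spec$levels[[v]]
      f <- factor(as.character(data[[v]]), levels = lev)
      for (l in lev[-1]) out[[paste0(v, l)]] <- as.numeric(f == l)
    } else {
      out[[v]] <- as.numeric(data[[v]])
    }
  }
  out
}

# Expand one variable into its design columns. Returns a named list of
# numeric columns; `linear_of` gives the single linear/dummy block used in
# product terms.
variable_columns <- function(v, data, spec) {
  col <- data[[v]]
  if (!is.null(spec$levels[[v]])) {
    lev <- spec$levels[[v]]
    f <- factor(as.character(col), levels = lev)
    if (anyNA(f) && !anyNA(col)) abort(paste0("new level in `", v, "` not seen at fit time"))
    cols <- list()
    for (l in lev[-1]) cols[[paste0(v, l)]] <- as.numeric(f == l)
    cols
  } else if (v %in% names(spec$knots)) {
    b <- rcs_basis(as.numeric(col), spec$knots[[v]])
    out <- lapply(seq_len(ncol(b)), function(j) b[, j])
    # name pattern: v, v', v'', ...
    names(out) <- c(v, if (ncol(b) > 1) paste0(v, strrep("'", seq_len(ncol(b) - 1))))
    out
  } else {
    setNames(list(as.numeric(col)), v)
  }
}

#' Build a hazard-model design matrix
#'
#' Constructs the design matrix described by a (resolved) [design_spec()]
#' from a person-period table: intercept, time basis, exposure basis,
#' covariate main effects, and the configured product blocks, in a fixed
#' deterministic column order. Rank deficiency is not checked here; the
#' fitter raises a hard error naming the offending columns.
#'
#' @param data Person-period data frame containing `k`, the exposures, and
#'   all covariates named in the spec.
#' @param spec A resolved `design_spec` (as stored in fitted models). An
#'   unresolved spec is resolved against `data`.
#' @return Numeric matrix with named columns; attribute `"z_structure"`
#'   records, for each exposure-dependent column, its exposure scalar and
#'   row multiplier (used by the fast fixed-composition risk path).
#' @export
build_design <- function(data, spec) {
  if (is.null(spec$knots)) spec <- resolve_design(spec, data)
  n <- nrow(data)
  cols <- list(`(Intercept)` = rep(1, n))
  zinfo <- list() # only exposure-dependent columns are recorded

  # time basis
  if (spec$time_type == "none") {
    # no time columns
  } else if (spec$time_type == "factor") {
    for (l in spec$k_levels[-1]) {
      cols[[paste0("k", l)]] <- as.numeric(data$k == l)
    }
  } else {
    tv <- variable_columns("k", data, spec)
    for (nm in names(tv)) cols[[nm]] <- tv[[nm]]
  }

  # exposure basis: record scalar id (coord, basis index) for the fast path
  for (j in seq_along(spec$exposures)) {
    v <- spec$exposures[j]
    ev <- variable_columns(v, data, spec)
    for (b in seq_along(ev)) {
      nm <- names(ev)[b]
      cols[[nm]] <- ev[[b]]
      zinfo[[nm]] <- list(coord = v, basis = b, multiplier = "1")
    }
  }

  # covariate mains
  for (v in spec$covariates) {
    cv <- variable_columns(v, data, spec)
    for (nm in names(cv)) cols[[nm]] <- cv[[nm]]
  }

  k_lin <- if (spec$time_type == "none") NULL else as.numeric(data[["k"]])
  keys <- key_linear_columns(data, spec)

  if (isTRUE(spec$exposure_time) && spec$time_type != "none") {
    if (spec$time_type == "factor") {
      for (v in spec$exposures) {
        for (l in spec$k_levels[-1]) {
          nm <- paste0(v, ":k", l)
          cols[[nm]] <- as.numeric(data[[v]]) * as.numeric(data$k == l)
          zinfo[[nm]] <- list(coord = v, basis = 1L, multiplier = paste0("k==", l))
        }
      }
    } else {
      for (v in spec$exposures) {
        nm <- paste0(v, ":k")
        cols[[nm]] <- as.numeric(data[[v]]) * k_lin
        zinfo[[nm]] <- list(coord = v, basis = 1L, multiplier = "k")
      }
    }
  }
  if (isTRUE(spec$exposure_key) && length(keys) > 0) {
    for (v in spec$exposures) {
      for (kn in names(keys)) {
        nm <- paste0(v, ":", kn)
        cols[[nm]] <- as.numeric(data[[v]]) * keys[[kn]]
        zinfo[[nm]] <- list(coord = v, basis = 1L, multiplier = paste0("cov:", kn))
      }
    }
  }
  if (isTRUE(spec$key_time) && length(keys) > 0 && spec$time_type != "none") {
    if (spec$time_type == "factor") {
      for (kn in names(keys)) {
        for (l in spec$k_levels[-1]) {
          nm <- paste0(kn, ":k", l)
          cols[[nm]] <- keys[[kn]] * as.numeric(data$k == l)
        }
      }
    } else {
      for (kn in names(keys)) {
        nm <- paste0(kn, ":k")
        cols[[nm]] <- keys[[kn]] * k_lin
      }
    }
  }

  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  attr(X, "z_structure") <- zinfo
  X
}

# Number of exposure basis columns (per coordinate) implied by a resolved
# spec; used by the fast fixed-composition path.
exposure_basis_values <- function(spec, z) {
  # z: named numeric (z1, z2, z3). Returns named vector of scalar values for
  # each (coord, basis) pair appearing in the design.
  vals <- c()
  for (v in spec$exposures) {
    if (v %in% names(spec$knots)) {
      b <- rcs_basis(z[[v]], spec$knots[[v]])
      vals[paste0(v, ".", seq_len(ncol(b)))] <- b[1, ]
    } else {
      vals[paste0(v, ".1")] <- z[[v]]
    }
  }
  vals
}
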