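# Cross-validated search over a 15-minute lattice of synthetic 24-hour
# compositions for the lowest-risk, highest-risk, and typical
# compositions. Rare or implausible lattice points (too few sample
# neighbours within an Aitchison radius) are excluded; training-fold risks
# select the extremes and the testing fold re-estimates their risks,
# protecting against over-optimism.

#' Build a lattice of synthetic compositions
#'
#' Enumerates all compositions whose sleep, inactivity, and light minutes
#' are multiples of `step` inside their sample ranges, with MVPA set by
#' difference to 1440 and required to be a positive multiple of `step`
#' within its own range. Ordering is deterministic (lexicographic in
#' sleep, inactivity, light).
#'
#' @param range Sample range from [compute_sample_range()].
#' @param step Lattice step in minutes (default 15).
#' @return A `composition_grid` tibble with the four behaviour columns.
#' @export
build_grid <- function(range, step = 15) {
  lo <- setNames(range$min, range$behavior)
  hi <- setNames(range$max, range$behavior)
  lattice <- function(b) {
    from <- ceiling(lo[[b]] / step) * step
    to <- floor(hi[[b]] / step) * step
    if (from > to) numeric(0) else seq(from, to, by = step)
  }
  g <- tidyr::expand_grid(
    sleep_min = lattice("sleep"),
    inactivity_min = lattice("inactivity"),
    light_min = lattice("light")
  )
  g$mvpa_min <- 1440 - g$sleep_min - g$inactivity_min - g$light_min
  g <- g[g$mvpa_min >= max(lo[["mvpa"]], step) & g$mvpa_min <= hi[["mvpa"]], , drop = FALSE]
  if (nrow(g) == 0) {
    abort(paste0(
      "empty composition grid for step ", step, " min; ranges: ",
      paste(range$behavior, sprintf("[%.0f, %.0f]", range$min, range$max), collapse = ", ")
    ))
  }
  g <- arrange(g, .data$sleep_min, .data$inactivity_min, .data$light_min)
  class(g) <- c("composition_grid", class(g))
  g
}

# Count, for each grid point, cohort members within `radius` in ILR space.
ilr_neighbor_counts <- function(grid, cohort, radius, chunk = 512) {
  zg <- ilr_transform(as_behavior_matrix(grid))
  zc <- ilr_transform(as_behavior_matrix(cohort))
  r2 <- radius^2
  counts <- integer(nrow(zg))
  cross <- tcrossprod(zg, zc) # G x n
  ng2 <- rowSums(zg^2)
  nc2 <- rowSums(zc^2)
  for (start in seq(1, nrow(zg), by = chunk)) {
    idx <- start:min(start + chunk - 1, nrow(zg))
    d2 <- outer(ng2[idx], nc2, "+") - 2 * cross[idx, , drop = FALSE]
    counts[idx] <- rowSums(d2 <= r2)
  }
  counts
}

#' Exclude rare or implausible grid compositions
#'
#' Retains lattice points with at least `min_neighbors` cohort members
#' within `radius` (Aitchison distance) — a sample-density criterion for
#' plausibility.
#'
#' @param grid A [build_grid()] result.
#' @param cohort Analysis cohort with the behaviour columns.
#' @param min_neighbors Minimum neighbour count.
#' @param radius Aitchison-distance radius.
#' @return The grid tibble with columns `n_neighbors` and `retained`.
#' @export
plausibility_filter <- function(grid, cohort, min_neighbors = 10, radius = 0.25) {
  counts <- ilr_neighbor_counts(grid, cohort, radius)
  out <- as_tibble(grid)
  out$n_neighbors <- counts
  out$retained <- counts >= min_neighbors
  if (!any(out$retained)) {
    abort("every grid point was filtered out; increase `radius` or lower `min_neighbors`")
  }
  class(out) <- c("composition_grid", class(out))
  out
}

# Nearest retained grid point (ILR metric) for each cohort member.
nearest_grid_point <- function(grid, cohort, chunk = 2048) {
  zg <- ilr_transform(as_behavior_matrix(grid))
  zc <- ilr_transform(as_behavior_matrix(cohort))
  ng2 <- rowSums(zg^2)
  nearest <- integer(nrow(zc))
  for (start in seq(1, nrow(zc), by = chunk)) {
    idx <- start:min(start + chunk - 1, nrow(zc))
    d2 <- outer(rowSums(zc[idx, , drop = FALSE]^2), ng2, "+") -
      2 * tcrossprod(zc[idx, , drop = FALSE], zg)
    nearest[idx] <- max.col(-d2, ties.method = "first")
  }
  nearest
}

#' Most common (typical) grid composition
#'
#' Assigns every cohort member to their nearest retained grid point in ILR
#' space and returns the point with the largest count. Ties break first by
#' smaller Aitchison distance to the cohort's ILR mean, then by grid
#' order.
#'
#' @inheritParams plausibility_filter
#' @return One-row tibble with the four behaviour columns.
#' @export
find_typical <- function(grid, cohort) {
  g <- if ("retained" %in% names(grid)) grid[grid$retained, , drop = FALSE] else as_tibble(grid)
  if (nrow(g) == 0) abort("no retained grid points")
  nearest <- nearest_grid_point(g, cohort)
  counts <- tabulate(nearest, nbins = nrow(g))
  zg <- ilr_transform(as_behavior_matrix(g))
  zmean <- colMeans(ilr_transform(as_behavior_matrix(cohort)))
  d_center <- sqrt(colSums((t(zg) - zmean)^2))
  ord <- order(-counts, d_center, seq_len(nrow(g)))
  g[ord[1], behavior_cols()]
}

# Fast g-formula risk at fixed grid compositions. The design is affine in
# the exposure basis values once covariates and time are fixed, so the
# linear predictor over all grid points is one matrix product:
# lp = A + B %*% svals(z), with A the exposure-free part and B assembled
# from the exposure-dependent columns' row multipliers.
fixed_composition_lp_parts <- function(fit, newdata) {
  spec <- fit$spec
  X <- build_design(newdata, spec)
  zinfo <- attr(X, "z_structure")
  beta <- fit$coef
  zfree <- !(colnames(X) %in% names(zinfo))
  A <- as.numeric(X[, zfree, drop = FALSE] %*% beta[zfree])
  ids <- character(0)
  for (nm in names(zinfo)) {
    ids <- union(ids, paste0(zinfo[[nm]]$coord, ".", zinfo[[nm]]$basis))
  }
  keys <- key_linear_columns(newdata, spec)
  mult <- function(tag) {
    if (tag == "1") rep(1, nrow(newdata))
    else if (tag == "k") as.numeric(newdata$k)
    else if (startsWith(tag, "k==")) as.numeric(newdata$k == as.numeric(sub("k==", "", tag)))
    else if (startsWith(tag, "cov:")) keys[[sub("cov:", "", tag)]]
    else abort("unknown multiplier tag")
  }
  B <- matrix(0, nrow(newdata), length(ids), dimnames = list(NULL, ids))
  for (nm in names(zinfo)) {
    zi <- zinfo[[nm]]
    id <- paste0(zi$coord, ".", zi$basis)
    B[, id] <- B[, id] + beta[[nm]] * mult(zi$multiplier)
  }
  list(A = A, B = B, ids = ids, spec = spec)
}

# Risks F(K) for every grid composition, standardized over `cohort`.
grid_risks <- function(cohort, fits, grid, K, chunk = 128) {
  cohort <- add_ilr(as_tibble(cohort),
    contrast = fits$dementia$spec$contrast %||% ilr_contrast_matrix()
  )
  n <- nrow(cohort)
  newdata <- cohort[rep(seq_len(n), each = K), , drop = FALSE]
  newdata$k <- rep(seq_len(K), times = n)
  pY <- fixed_composition_lp_parts(fits$dementia, newdata)
  pD <- fixed_composition_lp_parts(fits$death, newdata)
  zg <- ilr_transform(as_behavior_matrix(close_composition(as_behavior_matrix(grid))),
    contrast = fits$dementia$spec$contrast %||% ilr_contrast_matrix()
  )
  sval_matrix <- function(parts) {
    S <- matrix(0, nrow(zg), length(parts$ids), dimnames = list(NULL, parts$ids))
    for (id in parts$ids) {
      coord <- sub("\\.[0-9]+$", "", id)
      basis <- as.integer(sub("^z[0-9]+\\.", "", id))
      zcol <- zg[, coord]
      if (coord %in% names(parts$spec$knots)) {
        S[, id] <- rcs_basis(zcol, parts$spec$knots[[coord]])[, basis]
      } else {
        S[, id] <- zcol
      }
    }
    S
  }
  SY <- sval_matrix(pY)
  SD <- sval_matrix(pD)
  G <- nrow(zg)
  risks <- numeric(G)
  for (start in seq(1, G, by = chunk)) {
    idx <- start:min(start + chunk - 1, G)
    lpY <- pY$A + pY$B %*% t(SY[idx, , drop = FALSE])
    lpD <- pD$A + pD$B %*% t(SD[idx, , drop = FALSE])
    hY <- plogis(lpY) # (nK) x Gc, rows person-major
    hD <- plogis(lpD)
    surv <- matrix(1, n, length(idx))
    acc <- matrix(0, n, length(idx))
    for (k in seq_len(K)) {
      rows <- seq(k, n * K, by = K)
      hYk <- hY[rows, , drop = FALSE]
      hDk <- hD[rows, , drop = FALSE]
      acc <- acc + surv * (1 - hDk) * hYk
      surv <- surv * (1 - hDk) * (1 - hYk)
    }
    risks[idx] <- colMeans(acc)
  }
  risks
}

#' Cross-validated lowest/typical/highest-risk compositions
#'
#' Splits the cohort into two equal person-level folds, fits the hazard
#' models on the training fold, estimates g-formula dementia risk with
#' every retained grid composition assigned to the whole training fold,
#' and selects the compositions with the lowest and highest risks. The
#' typical composition is the most common retained point over the full
#' cohort. The testing fold then re-fits the models and re-estimates the
#' risks of the three selected compositions, so selection and evaluation
#' use disjoint data.
#'
#' @param cohort Analysis cohort (one row per person).
#' @param spec A [design_spec()] for the hazard models.
#' @param K Number of intervals.
#' @param seed Integer seed for the fold split.
#' @param grid Optional pre-built (and pre-filtered) grid; by default
#'   built from the cohort's sample range at `step` minutes and filtered.
#' @param step,min_neighbors,radius Grid and plausibility parameters.
#' @param interval_days Interval length for person-period expansion.
#' @return Object of class `composition_selection`: `lowest`, `highest`,
#'   `typical` (one-row composition tibbles), `grid` (with `train_risk`),
#'   `test_risks`, `train_risks`, and the fold assignment.
#' @export
crossvalidated_selection <- function(cohort, spec = design_spec(), K, seed = 1,
                                     grid = NULL, step = 15,
                                     min_neighbors = 10, radius = 0.25,
                                     interval_days = 365.25) {
  cohort <- as_tibble(cohort)
  n <- nrow(cohort)
  fold <- withr::with_seed(seed, sample(rep(1:2, length.out = n)))
  if (is.null(grid)) {
    range <- compute_sample_range(cohort)
    grid <- plausibility_filter(build_grid(range, step), cohort,
      min_neighbors = min_neighbors, radius = radius
    )
  }
  if (!"retained" %in% names(grid)) grid$retained <- TRUE
  retained <- grid[grid$retained, , drop = FALSE]
  typical <- find_typical(grid, cohort)

  fit_fold <- function(f) {
    members <- cohort[fold == f, , drop = FALSE]
    pp <- expand_person_periods(members, interval_days = interval_days, K = K)
    if (sum(pp$dementia) == 0 || sum(pp$death) == 0) {
      abort(paste0("fold ", f, " contains no events of one type; use a larger cohort"))
    }
    list(members = members, fits = fit_hazard_models(pp, spec))
  }
  train <- fit_fold(1)
  test <- fit_fold(2)

  train_risk <- grid_risks(train$members, train$fits, retained[behavior_cols()], K)
  i_low <- which.min(train_risk)
  i_high <- which.max(train_risk)
  lowest <- retained[i_low, behavior_cols()]
  highest <- retained[i_high, behavior_cols()]

  selections <- bind_rows(
    lowest = lowest, typical = typical, highest = highest,
    .id = "which"
  )
  test_risk <- grid_risks(test$members, test$fits, selections[behavior_cols()], K)
  test_risks <- mutate(selections, risk = test_risk)
  train_sel <- grid_risks(train$members, train$fits, selections[behavior_cols()], K)
  train_risks <- mutate(selections, risk = train_sel)

  grid_out <- as_tibble(grid)
  grid_out$train_risk <- NA_real_
  grid_out$train_risk[grid_out$retained] <- train_risk

  structure(
    list(
      lowest = lowest, highest = highest, typical = typical,
      grid = grid_out, train_risks = train_risks, test_risks = test_risks,
      fold = fold, K = K, seed = seed
    ),
    class = "composition_selection"
  )
}

#' @export
print.composition_selection <- function(x, ...) {
  cat("<composition_selection> (", sum(x$grid$retained), "retained grid points )\n")
  fmt <- function(row) paste(behaviors(), "=", round(as.numeric(row[behavior_cols()])), collapse = ", ")
  cat("  lowest: ", fmt(x$lowest), "\n")
  cat("  typical:", fmt(x$typical), "\n")
  cat("  highest:", fmt(x$highest), "\n")
  cat("  test-fold risks:", paste(x$test_risks$which, "=",
    signif(x$test_risks$risk, 3),
    collapse = ", "
  ), "\n")
  invisible(x)
}

#' @export
autoplot.composition_selection <- function(object, ...) {
  df <- object$test_risks |>
    tidyr::pivot_longer(dplyr::all_of(behavior_cols()),
      names_to = "behavior", values_to = "minutes"
    ) |>
    mutate(
      behavior = factor(sub("_min$", "", .data$behavior), levels = behaviors()),
      which = factor(.data$which, levels = c("lowest", "typical", "highest"))
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$which, y = .data$minutes / 60, fill = .data$behavior)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Hours per day", fill = "Behaviour") +
    ggplot2::theme_minimal()
}
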