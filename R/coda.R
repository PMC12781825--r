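# Compositional algebra for the 24-hour day.
#
# The day is a 4-part composition (sleep, inactivity, light, mvpa) closed to
# 1440 minutes. The ILR basis is the pivot (sequential binary partition)
# (sleep | inactivity, light, mvpa), (inactivity | light, mvpa),
# (light | mvpa): z1 contrasts sleep against waking time, z2 inactivity
# against activity, z3 light against MVPA. Any full-rank ILR basis gives
# identical model fits; this one is the package default and can be swapped
# by supplying another contrast matrix to the low-level helpers.

#' Behaviour names and column names
#'
#' The four behaviours of the 24-hour composition, in the fixed pivot order,
#' and the cohort column names holding their minutes per day.
#'
#' @return Character vector of length four.
#' @export
#' @examples
#' behaviors()
#' behavior_cols()
behaviors <- function() c("sleep", "inactivity", "light", "mvpa")

#' @rdname behaviors
#' @export
behavior_cols <- function() paste0(behaviors(), "_min")

#' Pivot-coordinate contrast matrix
#'
#' The 3x4 orthonormal contrast matrix `V` such that `z = V %*% log(p)` for a
#' proportion vector `p` in pivot order (sleep, inactivity, light, mvpa).
#'
#' @return A 3x4 numeric matrix with orthonormal rows.
#' @export
ilr_contrast_matrix <- function() {
  rbind(
    sqrt(3 / 4) * c(1, -1 / 3, -1 / 3, -1 / 3),
    sqrt(2 / 3) * c(0, 1, -1 / 2, -1 / 2),
    sqrt(1 / 2) * c(0, 0, 1, -1)
  )
}

# Coerce compositions to an n x 4 matrix in pivot order. Accepts a data
# frame with sleep_min..mvpa_min columns, a 4-column matrix, or a length-4
# numeric vector (optionally named by behaviour).
as_behavior_matrix <- function(x) {
  cols <- behavior_cols()
  if (is.data.frame(x)) {
    missing <- setdiff(cols, names(x))
    if (length(missing) > 0) {
      abort(paste0("composition columns missing: ", paste(missing, collapse = ", ")))
    }
    m <- as.matrix(x[cols])
  } else if (is.matrix(x)) {
    if (ncol(x) != 4) abort("composition matrix must have 4 columns")
    m <- x
    colnames(m) <- cols
  } else if (is.numeric(x) && length(x) == 4) {
    if (!is.null(names(x)) && all(behaviors() %in% names(x))) {
      x <- x[behaviors()]
    } else if (!is.null(names(x)) && all(cols %in% names(x))) {
      x <- x[cols]
    }
    m <- matrix(as.numeric(x), nrow = 1, dimnames = list(NULL, cols))
  } else {
    abort("composition must be a data frame, 4-column matrix, or length-4 numeric vector")
  }
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) abort("composition contains non-finite values")
  m
}

# Return result in the shape of the input: data frame in -> tibble with the
# behaviour columns replaced; vector in -> named vector; matrix -> matrix.
restore_behavior_shape <- function(x, m) {
  cols <- behavior_cols()
  if (is.data.frame(x)) {
    out <- as_tibble(x)
    out[cols] <- as_tibble(as.data.frame(m))
    out
  } else if (is.matrix(x)) {
    m
  } else {
    setNames(as.numeric(m[1, ]), cols)
  }
}

#' Close a composition to a fixed daily total
#'
#' Rescales the four behaviour parts to sum exactly to `total` minutes
#' (default the 1440-minute day). The last part is set by difference so the
#' sum is exact in floating point. Idempotent, and a no-op for compositions
#' already on the simplex.
#'
#' @param x A cohort data frame with `sleep_min`, `inactivity_min`,
#'   `light_min`, `mvpa_min` columns, a 4-column matrix, or a length-4
#'   numeric vector.
#' @param total Target daily total in minutes.
#' @return `x` with parts rescaled, same shape as the input.
#' @export
#' @examples
#' close_composition(c(180, 360, 105, 75))
close_composition <- function(x, total = 1440) {
  if (!is.numeric(total) || length(total) != 1 || !is.finite(total) || total <= 0) {
    abort("`total` must be a single positive number")
  }
  m <- as_behavior_matrix(x)
  if (any(m <= 0)) {
    abort("all composition parts must be strictly positive (zero parts are rejected)")
  }
  s <- rowSums(m)
  out <- m * (total / s)
  out[, 4] <- total - rowSums(out[, 1:3, drop = FALSE])
  restore_behavior_shape(x, out)
}

#' Isometric log-ratio (pivot coordinate) transform
#'
#' Maps compositions to three unconstrained balance coordinates:
#' `z1 = sqrt(3/4) log(p_sleep / gm(p_inact, p_light, p_mvpa))`,
#' `z2 = sqrt(2/3) log(p_inact / gm(p_light, p_mvpa))`,
#' `z3 = sqrt(1/2) log(p_light / p_mvpa)`, where `gm` is the geometric mean
#' and `p` are proportions of the day. Scale-invariant: parts need not be
#' closed beforehand.
#'
#' @inheritParams close_composition
#' @param contrast Orthonormal 3x4 contrast matrix; defaults to the package
#'   pivot basis [ilr_contrast_matrix()].
#' @return For data-frame input, a tibble with columns `z1`, `z2`, `z3`
#'   (one row per input row); for matrix input an n x 3 matrix; for vector
#'   input a named length-3 vector.
#' @seealso [ilr_inverse()], [add_ilr()]
#' @export
#' @examples
#' ilr_transform(c(360, 360, 360, 360)) # equal shares -> zero balances
ilr_transform <- function(x, contrast = ilr_contrast_matrix()) {
  m <- as_behavior_matrix(x)
  if (any(m <= 0)) abort("all composition parts must be strictly positive")
  p <- m / rowSums(m)
  z <- log(p) %*% t(contrast)
  colnames(z) <- paste0("z", seq_len(ncol(z)))
  if (is.data.frame(x)) {
    as_tibble(as.data.frame(z))
  } else if (is.matrix(x)) {
    z
  } else {
    setNames(as.numeric(z[1, ]), colnames(z))
  }
}

#' Inverse ILR transform
#'
#' Maps balance coordinates back to a composition closed to `total` minutes.
#' Exact inverse of [ilr_transform()] (round-trip error below 1e-10).
#'
#' @param z A data frame with columns `z1`, `z2`, `z3`, an n x 3 matrix, or
#'   a length-3 numeric vector.
#' @inheritParams ilr_transform
#' @inheritParams close_composition
#' @return Composition in the shape matching the input (tibble with the four
#'   behaviour columns, matrix, or named vector).
#' @export
#' @examples
#' ilr_inverse(c(0, 0, 0))
ilr_inverse <- function(z, total = 1440, contrast = ilr_contrast_matrix()) {
  if (is.data.frame(z)) {
    zm <- as.matrix(z[paste0("z", 1:3)])
  } else if (is.matrix(z)) {
    zm <- z
  } else if (is.numeric(z) && length(z) == 3) {
    zm <- matrix(as.numeric(z), nrow = 1)
  } else {
    abort("`z` must be a data frame with z1..z3, a 3-column matrix, or a length-3 vector")
  }
  storage.mode(zm) <- "double"
  if (any(!is.finite(zm))) abort("ILR coordinates must be finite")
  lp <- zm %*% contrast
  lp <- lp - apply(lp, 1, max) # overflow guard
  p <- exp(lp)
  m <- p / rowSums(p) * total
  m[, 4] <- total - rowSums(m[, 1:3, drop = FALSE])
  colnames(m) <- behavior_cols()
  if (is.data.frame(z)) {
    as_tibble(as.data.frame(m))
  } else if (is.matrix(z) && !is.null(dim(z))) {
    if (length(z) == 3 && nrow(zm) == 1 && !is.matrix(z)) m[1, ] else m
  } else {
    setNames(as.numeric(m[1, ]), behavior_cols())
  }
}

#' Add ILR coordinates to a cohort table
#'
#' Convenience verb: computes `z1`, `z2`, `z3` from the behaviour columns
#' and binds them to the cohort, replacing any existing z columns.
#'
#' @param cohort Data frame with the four behaviour columns.
#' @inheritParams ilr_transform
#' @return The cohort tibble with columns `z1`, `z2`, `z3`.
#' @export
add_ilr <- function(cohort, contrast = ilr_contrast_matrix()) {
  z <- ilr_transform(as_behavior_matrix(cohort), contrast = contrast)
  out <- as_tibble(cohort)
  out[colnames(z)] <- as_tibble(as.data.frame(z))
  out
}

#' Aitchison distance between compositions
#'
#' Euclidean distance in ILR space; the natural metric on the simplex.
#'
#' @param x,y Compositions (any form accepted by [ilr_transform()]);
#'   recycled rowwise if one has a single row.
#' @return Numeric vector of distances.
#' @export
aitchison_distance <- function(x, y) {
  zx <- ilr_transform(as_behavior_matrix(x))
  zy <- ilr_transform(as_behavior_matrix(y))
  if (nrow(zx) == 1 && nrow(zy) > 1) zx <- zx[rep(1, nrow(zy)), , drop = FALSE]
  if (nrow(zy) == 1 && nrow(zx) > 1) zy <- zy[rep(1, nrow(zx)), , drop = FALSE]
  sqrt(rowSums((zx - zy)^2))
}

#' Geometric-mean composition of a cohort
#'
#' Componentwise geometric mean of the behaviour minutes, closed to `total`.
#' This is the compositional centre reported in cohort descriptive tables.
#'
#' @inheritParams close_composition
#' @return Named length-4 numeric vector of minutes.
#' @export
geometric_mean_composition <- function(x, total = 1440) {
  m <- as_behavior_matrix(x)
  if (nrow(m) == 0) abort("cannot take the geometric mean of an empty cohort")
  if (any(m <= 0)) abort("all composition parts must be strictly positive")
  g <- exp(colMeans(log(m)))
  close_composition(g, total = total)
}

#' Standardize wear days over the day of the week
#'
#' Collapses per-day behaviour records to one composition per person,
#' weighting the weekday (Mon-Fri) mean by 5/7 and the weekend (Sat-Sun)
#' mean by 2/7 so that people measured on different days of the week are
#' comparable. A person with only one stratum observed falls back to that
#' stratum's mean and is flagged. Day-level sums may deviate from 1440
#' minutes (device non-wear); each day must total within `sum_range`, and
#' the weighted result is closed to 1440.
#'
#' @param days Data frame with columns `pid`, `dow` (1 = Monday .. 7 =
#'   Sunday) and the four behaviour columns.
#' @param sum_range Acceptable per-day total minutes before closure.
#' @return Tibble with one row per person: `pid`, the four behaviour
#'   columns (closed to 1440), and `dow_fallback` (TRUE when only one of
#'   the weekday/weekend strata was observed).
#' @export
standardize_week <- function(days, sum_range = c(1200, 1680)) {
  if (!is.data.frame(days) || nrow(days) == 0) abort("`days` must be a non-empty data frame")
  need <- c("pid", "dow", behavior_cols())
  missing <- setdiff(need, names(days))
  if (length(missing) > 0) abort(paste0("day-level columns missing: ", paste(missing, collapse = ", ")))
  if (!all(days$dow %in% 1:7)) abort("`dow` must be in 1..7 (1 = Monday)")
  m <- as_behavior_matrix(days)
  if (any(m < 0)) abort("day-level minutes must be nonnegative")
  tot <- rowSums(m)
  bad <- tot < sum_range[1] | tot > sum_range[2]
  if (any(bad)) {
    abort(paste0(
      sum(bad), " day record(s) have totals outside [", sum_range[1], ", ",
      sum_range[2], "] minutes; first offending pid: ", days$pid[which(bad)[1]]
    ))
  }
  days <- as_tibble(days)
  days$.weekend <- days$dow >= 6
  stratum_means <- days |>
    group_by(.data$pid, .data$.weekend) |>
    summarise(across(dplyr::all_of(behavior_cols()), mean), .groups = "drop")
  per_person <- stratum_means |>
    tidyr::pivot_wider(
      names_from = ".weekend", values_from = dplyr::all_of(behavior_cols()),
      names_glue = "{.value}.{.weekend}"
    )
  wk_cols <- paste0(behavior_cols(), ".FALSE")
  we_cols <- paste0(behavior_cols(), ".TRUE")
  for (col in c(wk_cols, we_cols)) if (!col %in% names(per_person)) per_person[[col]] <- NA_real_
  wk <- as.matrix(per_person[wk_cols])
  we <- as.matrix(per_person[we_cols])
  has_wk <- !is.na(wk[, 1])
  has_we <- !is.na(we[, 1])
  out <- matrix(NA_real_, nrow(per_person), 4, dimnames = list(NULL, behavior_cols()))
  both <- has_wk & has_we
  out[both, ] <- (5 / 7) * wk[both, , drop = FALSE] + (2 / 7) * we[both, , drop = FALSE]
  out[has_wk & !has_we, ] <- wk[has_wk & !has_we, , drop = FALSE]
  out[!has_wk & has_we, ] <- we[!has_wk & has_we, , drop = FALSE]
  res <- tibble(pid = per_person$pid)
  res[behavior_cols()] <- as.data.frame(close_composition(out))
  res$dow_fallback <- !(both)
  res
}

#' Trim compositional extremes from a cohort
#'
#' Removes every person whose time in *any* behaviour falls below the
#' `lower_pct` or above the `upper_pct` percentile of that behaviour in the
#' input cohort, limiting the influence of extreme values and device
#' errors. Percentiles use linear-interpolation quantiles (type 7) computed
#' once on the input cohort (not iteratively).
#'
#' @param cohort Cohort data frame with the four behaviour columns.
#' @param lower_pct,upper_pct Percentile bounds (defaults 0.1 and 99.9).
#' @return The retained rows as a tibble, with attribute `"trim_log"`
#'   (a tibble of per-behaviour exclusion counts and bounds) accessible via
#'   [trim_log()].
#' @export
trim_extremes <- function(cohort, lower_pct = 0.1, upper_pct = 99.9) {
  m <- as_behavior_matrix(cohort)
  if (nrow(m) < 1000) {
    warn("fewer than 1000 rows: tail percentiles are unstable")
  }
  lo <- apply(m, 2, quantile, probs = lower_pct / 100, type = 7, names = FALSE)
  hi <- apply(m, 2, quantile, probs = upper_pct / 100, type = 7, names = FALSE)
  below <- sweep(m, 2, lo, "<")
  above <- sweep(m, 2, hi, ">")
  drop <- rowSums(below | above) > 0
  log <- tibble(
    behavior = behaviors(),
    lower_bound = lo, upper_bound = hi,
    n_below = colSums(below), n_above = colSums(above)
  )
  if (all(drop)) warn("trimming removed every row")
  out <- as_tibble(cohort)[!drop, , drop = FALSE]
  attr(out, "trim_log") <- log
  out
}

#' @rdname trim_extremes
#' @param x A cohort returned by [trim_extremes()].
#' @export
trim_log <- function(x) attr(x, "trim_log")

#' Sleep-duration subgroup membership
#'
#' Adds logical membership flags for the sleep-duration subgroups used in
#' the substitution analyses: short (< 6 h), normal (>= 6 h and <= 9 h), and
#' long (> 8 h, a secondary subgroup). Normal and long overlap on (8 h, 9 h],
#' so a person may belong to two subgroups; no one with positive sleep is
#' unlabelled.
#'
#' @param cohort Cohort data frame with a `sleep_min` column.
#' @return The cohort tibble with logical columns `sleep_short`,
#'   `sleep_normal`, `sleep_long`.
#' @export
#' @examples
#' assign_sleep_group(tibble::tibble(
#'   sleep_min = c(355, 390, 510, 560),
#'   inactivity_min = 700, light_min = 200, mvpa_min = 100
#' ))
assign_sleep_group <- function(cohort) {
  if (!"sleep_min" %in% names(cohort)) abort("cohort must have a `sleep_min` column")
  out <- as_tibble(cohort)
  s <- out$sleep_min
  out$sleep_short <- s < 360
  out$sleep_normal <- s >= 360 & s <= 540
  out$sleep_long <- s > 480
  out
}

#' @rdname assign_sleep_group
#' @param group One of `"short"`, `"normal"`, `"long"`, or `"all"`.
#' @return For `subgroup_members()`, a logical vector of membership.
#' @export
subgroup_members <- function(cohort, group = c("normal", "short", "long", "all")) {
  group <- arg_match(group)
  s <- cohort$sleep_min
  switch(group,
    short = s < 360,
    normal = s >= 360 & s <= 540,
    long = s > 480,
    all = rep(TRUE, length(s))
  )
}
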