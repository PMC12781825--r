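# Isotemporal substitution logic: +/- delta reallocation between two
# behaviours, per-person feasibility against the analysis-sample range, the
# 75% reporting rule, and the full subgroup x pair x delta risk-ratio
# matrix.

#' Apply an isotemporal substitution to compositions
#'
#' Adds `delta` minutes to `to` and subtracts `delta` from `from`, leaving
#' the other behaviours (and the 1440-minute total) unchanged. A row whose
#' `from` part would become non-positive is infeasible; its output parts
#' are NA and it is flagged in the `.feasible_positive` column.
#'
#' @param cohort Cohort data frame with the behaviour columns.
#' @param from,to Behaviour names.
#' @param delta Minutes to reallocate; a positive multiple of 15 up to 60
#'   in the primary analyses (other positive values are allowed).
#' @return Tibble with the substituted behaviour columns and
#'   `.feasible_positive`.
#' @export
#' @examples
#' apply_substitution(
#'   tibble::tibble(
#'     sleep_min = 390, inactivity_min = 720,
#'     light_min = 225, mvpa_min = 105
#'   ),
#'   from = "light", to = "sleep", delta = 30
#' )
apply_substitution <- function(cohort, from, to, delta) {
  stopifnot(from %in% behaviors(), to %in% behaviors())
  if (from == to) abort("`from` and `to` must differ")
  if (!is.numeric(delta) || length(delta) != 1 || delta <= 0) {
    abort("`delta` must be a single positive number of minutes")
  }
  m <- as_behavior_matrix(cohort)
  from_col <- paste0(from, "_min")
  to_col <- paste0(to, "_min")
  m[, from_col] <- m[, from_col] - delta
  m[, to_col] <- m[, to_col] + delta
  feasible <- m[, from_col] > 0
  m[!feasible, ] <- NA_real_
  out <- as_tibble(as.data.frame(m))
  out$.feasible_positive <- feasible
  out
}

#' Per-behaviour range of the analysis sample
#'
#' Minimum and maximum observed minutes for each behaviour over the full
#' (trimmed) analysis sample. Substituted compositions must stay inside
#' this axis-aligned box to be feasible.
#'
#' @param cohort Cohort data frame with the behaviour columns.
#' @return Tibble with columns `behavior`, `min`, `max`.
#' @export
compute_sample_range <- function(cohort) {
  m <- as_behavior_matrix(cohort)
  if (nrow(m) == 0) abort("empty cohort: no sample range")
  lo <- apply(m, 2, min)
  hi <- apply(m, 2, max)
  if (any(lo >= hi)) {
    abort("degenerate sample range (min >= max for some behaviour); need a larger cohort")
  }
  tibble(behavior = behaviors(), min = unname(lo), max = unname(hi))
}

# Check an n x 4 matrix of compositions against a sample-range tibble.
within_sample_range <- function(m, range) {
  lo <- setNames(range$min, range$behavior)[behaviors()]
  hi <- setNames(range$max, range$behavior)[behaviors()]
  ok <- rep(TRUE, nrow(m))
  for (j in 1:4) {
    ok <- ok & m[, j] >= lo[j] & m[, j] <= hi[j]
  }
  ok & !is.na(ok)
}

#' Per-person feasibility of a substitution
#'
#' A substitution is feasible for a person when the substituted composition
#' exists (the donor behaviour stays positive) and every behaviour of the
#' result lies within the per-behaviour `[min, max]` of the analysis
#' sample.
#'
#' @inheritParams apply_substitution
#' @param range Sample range from [compute_sample_range()]; NULL skips the
#'   range check (positivity only).
#' @return Logical vector, one element per row of `cohort`.
#' @export
feasibility_mask <- function(cohort, from, to, delta, range = NULL) {
  sub <- apply_substitution(cohort, from, to, delta)
  feas <- sub$.feasible_positive
  if (!is.null(range)) {
    m <- as.matrix(sub[behavior_cols()])
    inr <- within_sample_range(m, range)
    feas <- feas & inr
  }
  feas
}

default_pairs <- function() {
  tibble(
    from = c("inactivity", "sleep", "light", "sleep", "mvpa", "sleep"),
    to = c("sleep", "inactivity", "sleep", "light", "sleep", "mvpa")
  )
}

#' Substitution risk-ratio matrix
#'
#' For each sleep-duration subgroup, each ordered behaviour pair, and each
#' reallocation size, estimates the g-formula dementia risk under the
#' substitution regime and the risk ratio against the subgroup's
#' observed-composition reference. Hazard models are fitted once on the
#' full cohort; subgroups enter as standardization populations. A cell is
#' `presented` only when at least 75% of the subgroup can receive the
#' substitution; suppressed cells keep their computed values for audit.
#'
#' @param cohort Analysis cohort (one row per person, trimmed).
#' @param fits `hazard_models` fitted on the full cohort.
#' @param K Number of intervals for the cumulative incidence.
#' @param range Sample range; computed from `cohort` when NULL.
#' @param subgroups Character vector among `"short"`, `"normal"`, `"long"`,
#'   `"all"`.
#' @param pairs Tibble with columns `from`, `to`; defaults to the six
#'   ordered pairs between sleep and each waking behaviour.
#' @param deltas Reallocation sizes in minutes.
#' @param infeasible Passed to [regime_substitution()].
#' @param presented_threshold Minimum feasible fraction for presentation.
#' @return A `substitution_matrix` tibble: `subgroup`, `from`, `to`,
#'   `delta`, `risk_ref`, `risk_sub`, `rr`, `feasible_fraction`,
#'   `presented`.
#' @export
run_substitution_matrix <- function(cohort, fits, K,
                                    range = NULL,
                                    subgroups = c("short", "normal", "long"),
                                    pairs = default_pairs(),
                                    deltas = c(15, 30, 45, 60),
                                    infeasible = "observed",
                                    presented_threshold = 0.75) {
  if (is.null(range)) range <- compute_sample_range(cohort)
  cohort <- as_tibble(cohort)
  cells <- tidyr::expand_grid(pair = seq_len(nrow(pairs)), delta = deltas)
  regimes <- purrr::map2(cells$pair, cells$delta, function(i, d) {
    regime_substitution(pairs$from[i], pairs$to[i], d,
      range = range, infeasible = infeasible
    )
  })
  # one shared design decomposition over the full cohort; subgroups are
  # standardization populations (numerically identical to per-subgroup
  # estimate_risk calls)
  eng <- multi_regime_risk(cohort, fits, regimes, K)
  rows <- list()
  for (sg in subgroups) {
    members <- which(subgroup_members(cohort, sg))
    if (length(members) == 0) next
    risk_ref <- mean(eng$Fi[members, 1])
    for (j in seq_along(regimes)) {
      kept <- members[eng$keep[members, j + 1]]
      risk_sub <- mean(eng$Fi[kept, j + 1])
      ff <- mean(eng$feasible[members, j + 1])
      rows[[length(rows) + 1]] <- tibble(
        subgroup = sg,
        from = pairs$from[cells$pair[j]], to = pairs$to[cells$pair[j]],
        delta = cells$delta[j], risk_ref = risk_ref, risk_sub = risk_sub,
        rr = risk_sub / risk_ref,
        feasible_fraction = ff,
        presented = ff >= presented_threshold
      )
    }
  }
  out <- bind_rows(rows)
  class(out) <- c("substitution_matrix", class(out))
  out
}

#' @export
autoplot.substitution_matrix <- function(object, presented_only = FALSE, ...) {
  df <- as_tibble(object)
  if (presented_only) df <- df[df$presented, , drop = FALSE]
  df$pair <- paste(df$from, "→", df$to)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$delta, y = .data$rr)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$presented)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$subgroup),
      cols = ggplot2::vars(.data$pair)
    ) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    ggplot2::labs(
      x = "Minutes reallocated per day", y = "Dementia risk ratio",
      shape = "Presented (≥ 75% feasible)"
    ) +
    ggplot2::theme_minimal()
  if (all(c("conf.low", "conf.high") %in% names(df))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high),
      width = 2
    )
  }
  p
}
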