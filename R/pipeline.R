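# End-to-end orchestration: simulate (or read) a cohort, prepare it (trim,
# impute, ILR, sleep groups), fit the hazard models, run the substitution
# matrix with bootstrap intervals, search for the lowest/typical/highest
# risk compositions, run the MRI g-computation, and collect everything in
# a reproducible report keyed by a configuration hash.

#' Pipeline configuration
#'
#' Collects every analysis setting and seed so that a run is fully
#' reproducible: identical configurations produce byte-identical result
#' tables. Either `input_csv` (a cohort file in the package's cohort
#' schema) or simulation settings (`n`, `truth`) must be supplied.
#'
#' @param n Cohort size when simulating.
#' @param truth A [truth_params()] object for simulation.
#' @param seed Master seed for every stochastic stage.
#' @param input_csv Optional path to a cohort CSV (overrides simulation).
#' @param interval_days,K Discrete-time structure.
#' @param spec A [design_spec()] for the hazard models.
#' @param subgroups,pairs,deltas Substitution-matrix settings.
#' @param ci_deltas Reallocation sizes that receive bootstrap intervals.
#' @param B Bootstrap replicates.
#' @param grid_step,min_neighbors,radius Composition-search settings.
#' @param mri_outcomes MRI outcome columns to analyse (present in the
#'   cohort); empty vector to skip the MRI stage.
#' @param impute Run PMM imputation (point estimate and per-replicate).
#' @param truncate_years Optional sensitivity analysis: drop persons with
#'   dementia events in the first this-many years.
#' @param trim Trim compositional extremes before analysis.
#' @return A `run_config` list.
#' @export
run_config <- function(n = 5000, truth = truth_default(), seed = 1,
                       input_csv = NULL,
                       interval_days = 365.25, K = 9,
                       spec = design_spec(covariates = c(
                         "age", "female", "apoe4", "education", "income"
                       )),
                       subgroups = c("short", "normal", "long"),
                       pairs = default_pairs(),
                       deltas = c(15, 30, 45, 60),
                       ci_deltas = 30,
                       B = 50,
                       grid_step = 15, min_neighbors = 10, radius = 0.25,
                       mri_outcomes = character(0),
                       impute = TRUE,
                       truncate_years = NULL,
                       trim = TRUE) {
  structure(
    list(
      n = n, truth = truth, seed = seed, input_csv = input_csv,
      interval_days = interval_days, K = K, spec = spec,
      subgroups = subgroups, pairs = pairs, deltas = deltas,
      ci_deltas = ci_deltas, B = B,
      grid_step = grid_step, min_neighbors = min_neighbors, radius = radius,
      mri_outcomes = mri_outcomes, impute = impute,
      truncate_years = truncate_years, trim = trim
    ),
    class = "run_config"
  )
}

#' Bundled demonstration configuration
#'
#' A complete, desk-scale run: 5000 simulated persons under the default
#' cohort-realistic truth, 50 bootstrap replicates for the 30-minute
#' substitution intervals, a 30-minute composition-search lattice, and the
#' hippocampal-volume MRI stage. Used by the worked example and the
#' end-to-end determinism checks.
#'
#' @param seed Master seed.
#' @return A [run_config()].
#' @export
demo_config <- function(seed = 1) {
  run_config(
    n = 5000, truth = truth_default(), seed = seed,
    B = 50, grid_step = 30,
    mri_outcomes = "hippocampus_cm3"
  )
}

#' Read and write cohort CSV files
#'
#' The cohort schema is one row per person with columns `pid`, the four
#' behaviour columns (`sleep_min`, ...), covariates, and the event columns
#' `event_dem`, `time_dem`, `event_death`, `time_death`, `time_censor`
#' (times in days from baseline).
#'
#' @param path File path.
#' @param cohort Cohort tibble.
#' @return `read_cohort_csv()` returns a tibble; `write_cohort_csv()`
#'   returns `path` invisibly.
#' @export
read_cohort_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname read_cohort_csv
#' @export
write_cohort_csv <- function(cohort, path) {
  readr::write_csv(as_tibble(cohort), path)
  invisible(path)
}

#' Drop early dementia events (reverse-causation sensitivity analysis)
#'
#' Removes persons whose dementia event occurred within the first `years`
#' of follow-up; death and censoring are untouched. A substantial change
#' in the substitution risk ratios after this truncation would point to
#' reverse causation.
#'
#' @param cohort Cohort tibble.
#' @param years Truncation window in years.
#' @return The filtered tibble, with attribute `"n_truncated"`.
#' @export
truncate_early_events <- function(cohort, years = 3) {
  cohort <- as_tibble(cohort)
  early <- cohort$event_dem == 1 & cohort$time_dem < years * 365.25
  out <- cohort[!early, , drop = FALSE]
  attr(out, "n_truncated") <- sum(early)
  out
}

#' Run the full analysis pipeline
#'
#' Executes simulate/read -> prepare (trim, impute, ILR, sleep groups) ->
#' fit -> substitution matrix (+ bootstrap intervals on the `ci_deltas`
#' cells) -> composition search -> MRI g-computation, and returns a
#' report: all result tables, QC counts, and a configuration hash.
#' Identical configurations (including seeds) yield identical reports.
#'
#' @param config A [run_config()].
#' @param quiet Suppress progress messages.
#' @return Object of class `timeuse_report`.
#' @export
run_full_analysis <- function(config = run_config(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)
  t0 <- Sys.time()

  say("stage 1/6: cohort")
  if (!is.null(config$input_csv)) {
    cohort <- read_cohort_csv(config$input_csv)
  } else {
    cohort <- simulate_cohort(config$n,
      truth = config$truth, seed = config$seed,
      missingness = config$impute, mri = length(config$mri_outcomes) > 0
    )
  }
  n_input <- nrow(cohort)

  say("stage 2/6: prepare")
  if (!is.null(config$truncate_years)) {
    cohort <- truncate_early_events(cohort, config$truncate_years)
  }
  n_truncated <- attr(cohort, "n_truncated") %||% 0L
  trim_tab <- NULL
  if (isTRUE(config$trim)) {
    cohort <- trim_extremes(cohort)
    trim_tab <- trim_log(cohort)
  }
  impute_exclude <- unique(c(
    eval(formals(pmm_impute)$exclude), config$mri_outcomes
  ))
  cohort_raw <- assign_sleep_group(add_ilr(cohort))
  cohort <- if (config$impute) {
    assign_sleep_group(
      pmm_impute(cohort_raw, seed = config$seed, exclude = impute_exclude)
    )
  } else {
    cohort_raw
  }
  range <- compute_sample_range(cohort)

  say("stage 3/6: hazard models")
  pp <- expand_person_periods(cohort, interval_days = config$interval_days, K = config$K)
  spec <- resolve_design(config$spec, pp)
  fits <- fit_hazard_models(pp, spec)

  say("stage 4/6: substitutions")
  point_matrix <- run_substitution_matrix(
    cohort, fits, config$K,
    range = range, subgroups = config$subgroups,
    pairs = config$pairs, deltas = config$deltas
  )
  ci_tab <- NULL
  if (config$B >= 2 && length(config$ci_deltas) > 0) {
    if (config$impute) {
      # the nested scheme: resample the incomplete cohort, one imputation
      # per bootstrap sample, then refit (warm-started at the full fits)
      estimator <- substitution_estimator(config, range, spec, start = fits)
      boot <- suppressWarnings(bootstrap_pipeline(cohort_raw, estimator,
        B = config$B, seed = config$seed, impute = TRUE,
        impute_exclude = impute_exclude
      ))
      ci <- parse_substitution_estimands(boot)
    } else {
      regimes <- list()
      for (i in seq_len(nrow(config$pairs))) {
        for (d in config$ci_deltas) {
          regimes[[length(regimes) + 1]] <- regime_substitution(
            config$pairs$from[i], config$pairs$to[i], d,
            range = range
          )
        }
      }
      boot <- bootstrap_substitution_rr(
        cohort, config$spec, config$K, regimes,
        subgroups = config$subgroups, B = config$B, seed = config$seed,
        interval_days = config$interval_days
      )
      ci <- boot[c("subgroup", "from", "to", "delta", "conf.low", "conf.high")]
    }
    ci_tab <- boot
    point_matrix <- left_join(point_matrix, ci,
      by = c("subgroup", "from", "to", "delta")
    )
    class(point_matrix) <- c("substitution_matrix", class(as_tibble(point_matrix)))
  }

  say("stage 5/6: composition search")
  selection <- crossvalidated_selection(
    cohort,
    spec = config$spec, K = config$K, seed = config$seed,
    step = config$grid_step, min_neighbors = config$min_neighbors,
    radius = config$radius, interval_days = config$interval_days
  )

  say("stage 6/6: MRI")
  mri_md <- NULL
  mri_selected <- NULL
  if (length(config$mri_outcomes) > 0) {
    imaging <- cohort[!is.na(cohort[[config$mri_outcomes[1]]]), , drop = FALSE]
    md_rows <- list()
    sel_rows <- list()
    for (oc in config$mri_outcomes) {
      fit <- fit_linear_outcome(cohort, oc)
      for (sg in config$subgroups) {
        members <- imaging[subgroup_members(imaging, sg), , drop = FALSE]
        if (nrow(members) == 0) next
        for (i in seq_len(nrow(config$pairs))) {
          for (d in config$deltas) {
            md_rows[[length(md_rows) + 1]] <- mutate(
              gcomp_mean_difference(fit, members,
                config$pairs$from[i], config$pairs$to[i], d,
                range = range
              ),
              subgroup = sg
            )
          }
        }
      }
      sel_rows[[length(sel_rows) + 1]] <- mutate(
        predict_at_compositions(fit, imaging, selection$test_risks),
        outcome = oc
      )
    }
    mri_md <- bind_rows(md_rows)
    mri_selected <- bind_rows(sel_rows)
  }

  config_hash <- rlang::hash(config)
  structure(
    list(
      config = config,
      config_hash = config_hash,
      qc = tibble(
        n_input = n_input, n_truncated = n_truncated,
        n_analysis = nrow(cohort),
        n_dementia = sum(cohort$event_dem), n_death = sum(cohort$event_death)
      ),
      trim_log = trim_tab,
      sample_range = range,
      fits = fits,
      substitution = point_matrix,
      bootstrap = ci_tab,
      selection = selection,
      mri_md = mri_md,
      mri_selected = mri_selected,
      elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    ),
    class = "timeuse_report"
  )
}

# Estimator closure for the bootstrap: refits the hazard models on the
# resampled (re-imputed) cohort and recomputes the ci_deltas substitution
# RRs. The design spec is resolved once on the original cohort so knots
# and factor levels are shared across replicates.
substitution_estimator <- function(config, range, spec, start = NULL) {
  force(config)
  force(range)
  force(spec)
  force(start)
  function(cohort) {
    pp <- expand_person_periods(cohort,
      interval_days = config$interval_days, K = config$K
    )
    fits <- fit_hazard_models(pp, spec,
      start = start, check_rank = is.null(start), epsilon = 1e-8
    )
    tab <- run_substitution_matrix(
      cohort, fits, config$K,
      range = range, subgroups = config$subgroups,
      pairs = config$pairs, deltas = config$ci_deltas
    )
    setNames(
      tab$rr,
      paste("rr", tab$subgroup, tab$from, tab$to, tab$delta, sep = ".")
    )
  }
}

parse_substitution_estimands <- function(boot) {
  parts <- strsplit(boot$estimand, ".", fixed = TRUE)
  tibble(
    subgroup = vapply(parts, `[`, "", 2),
    from = vapply(parts, `[`, "", 3),
    to = vapply(parts, `[`, "", 4),
    delta = as.numeric(vapply(parts, `[`, "", 5)),
    conf.low = boot$conf.low,
    conf.high = boot$conf.high
  )
}

#' @export
print.timeuse_report <- function(x, ...) {
  cat("<timeuse_report>", x$config_hash, "\n")
  cat("  analysis n:", x$qc$n_analysis, " dementia events:", x$qc$n_dementia,
      " deaths:", x$qc$n_death, "\n")
  cat("  substitution cells:", nrow(x$substitution),
      " presented:", sum(x$substitution$presented), "\n")
  cat("  elapsed:", round(x$elapsed, 1), "s\n")
  invisible(x)
}

#' Write a report's tables to disk
#'
#' Writes tidy CSVs (substitution matrix, grid risks, QC, sample range,
#' MRI tables) and a JSON summary of the selected compositions. Every
#' table carries the configuration hash in a `config_hash` column, and
#' the files are byte-identical across runs of the same configuration.
#'
#' @param report A [run_full_analysis()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "timeuse_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  stamp <- function(df) mutate(as_tibble(df), config_hash = report$config_hash)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    readr::write_csv(stamp(df), p)
    paths <<- c(paths, p)
  }
  wr(report$qc, "qc.csv")
  wr(report$sample_range, "sample_range.csv")
  wr(report$substitution, "substitution_matrix.csv")
  wr(report$selection$grid, "composition_grid.csv")
  wr(bind_rows(
    train = report$selection$train_risks,
    test = report$selection$test_risks, .id = "fold"
  ), "selected_compositions.csv")
  if (!is.null(report$trim_log)) wr(report$trim_log, "trim_log.csv")
  if (!is.null(report$mri_md)) wr(report$mri_md, "mri_mean_differences.csv")
  if (!is.null(report$mri_selected)) wr(report$mri_selected, "mri_selected_compositions.csv")
  sel <- list(
    config_hash = report$config_hash,
    lowest = as.list(report$selection$lowest),
    typical = as.list(report$selection$typical),
    highest = as.list(report$selection$highest)
  )
  p <- file.path(dir, "selections.json")
  jsonlite::write_json(sel, p, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)
  invisible(paths)
}

#' Serialize a configuration to YAML
#'
#' Writes the scalar settings of a [run_config()] (not the truth object or
#' design spec, which are R structures reconstructed in code) for
#' provenance alongside a report.
#'
#' @param config A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config_yaml <- function(config, path) {
  scalars <- config[c(
    "n", "seed", "interval_days", "K", "subgroups", "deltas", "ci_deltas",
    "B", "grid_step", "min_neighbors", "radius", "mri_outcomes", "impute",
    "trim"
  )]
  scalars$truncate_years <- config$truncate_years %||% "none"
  yaml::write_yaml(scalars, path)
  invisible(path)
}
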