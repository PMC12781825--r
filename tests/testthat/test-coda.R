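# Compositional algebra: closure, ILR and its inverse, summaries,
# day-of-week standardization, trimming, and sleep-group assignment.

test_that("close_composition rescales to the 24-h total and is idempotent", {
  expect_equal(
    unname(close_composition(c(360, 720, 210, 150))),
    c(360, 720, 210, 150)
  )
  expect_equal(
    unname(close_composition(c(180, 360, 105, 75))),
    c(360, 720, 210, 150)
  )
  # the published highest-risk pattern (5 h sleep, 13.25 h inactivity,
  # 5 h light, 0.75 h MVPA) scaled down by half still closes to itself
  scaled <- c(300, 795, 300, 45) / 2
  expect_equal(unname(close_composition(scaled)), c(300, 795, 300, 45))
  once <- close_composition(c(123.4, 567.8, 90.1, 23.4))
  expect_equal(close_composition(once), once)
  expect_equal(sum(once), 1440)

  df <- tibble::tibble(
    pid = 1:2, sleep_min = c(180, 360), inactivity_min = c(360, 720),
    light_min = c(105, 210), mvpa_min = c(75, 150)
  )
  out <- close_composition(df)
  expect_s3_class(out, "tbl_df")
  expect_equal(out$pid, 1:2)
  expect_equal(out$sleep_min, c(360, 360))

  expect_error(close_composition(c(0, 720, 210, 150)), "positive")
  expect_error(close_composition(c(NaN, 720, 210, 150)), "finite")
})

test_that("ilr_transform matches the closed-form pivot balance formulas", {
  expect_equal(unname(ilr_transform(c(360, 360, 360, 360))), c(0, 0, 0))

  # independent oracle: direct evaluation of the three balances
  p <- c(360, 720, 210, 150) / 1440
  expected <- c(
    sqrt(3 / 4) * log(p[1] / (p[2] * p[3] * p[4])^(1 / 3)),
    sqrt(2 / 3) * log(p[2] / (p[3] * p[4])^(1 / 2)),
    sqrt(1 / 2) * log(p[3] / p[4])
  )
  expect_equal(unname(ilr_transform(c(360, 720, 210, 150))), expected,
    tolerance = 1e-12
  )
  expect_equal(unname(ilr_inverse(expected)), c(360, 720, 210, 150),
    tolerance = 1e-10
  )

  # the published "typical" day (6.5 h sleep / 12 h inactivity / 3.75 h
  # light / 1.75 h MVPA) maps to finite balances and inverts exactly
  typical <- c(390, 720, 225, 105)
  z <- ilr_transform(typical)
  expect_true(all(is.finite(z)))
  expect_equal(unname(ilr_inverse(z)), typical, tolerance = 1e-10)

  expect_error(ilr_transform(c(-1, 720, 210, 150)), "positive")
  expect_error(ilr_inverse(c(Inf, 0, 0)), "finite")
})

test_that("ILR round-trips, is scale invariant, and zero balances mean equal parts", {
  comps <- random_compositions(1000, seed = 42)
  z <- ilr_transform(comps)
  back <- ilr_inverse(z)
  expect_lt(max(abs(as.matrix(back[behavior_cols()]) - as.matrix(comps[behavior_cols()]))), 1e-10)

  m <- as.matrix(comps[behavior_cols()])
  expect_equal(ilr_transform(m), ilr_transform(m * 3.7), tolerance = 1e-12)

  expect_equal(unname(ilr_inverse(c(0, 0, 0))), rep(360, 4))
})

test_that("ILR is an isometry for the explicit Aitchison (clr) distance", {
  comps <- random_compositions(400, seed = 7)
  m <- as.matrix(comps[behavior_cols()])
  a <- m[1:200, ]
  b <- m[201:400, ]
  # independent oracle: Euclidean distance between clr images
  clr <- function(x) log(x) - rowMeans(log(x))
  d_oracle <- sqrt(rowSums((clr(a) - clr(b))^2))
  d_pkg <- aitchison_distance(a, b)
  expect_equal(d_pkg, d_oracle, tolerance = 1e-10)
})

test_that("geometric_mean_composition is the closed log-space average", {
  one <- c(390, 700, 230, 120)
  expect_equal(unname(geometric_mean_composition(one)), one, tolerance = 1e-10)

  # reciprocal-symmetric pair about equal shares averages to equal shares
  r <- c(2, 1 / 3, 3, 1 / 2)
  pair <- rbind(360 * r, 360 / r)
  expect_equal(unname(geometric_mean_composition(pair)), rep(360, 4),
    tolerance = 1e-10
  )

  comps <- random_compositions(500, seed = 3)
  m <- as.matrix(comps[behavior_cols()])
  # brute-force oracle: exp of columnwise mean log, then closure
  g <- exp(colMeans(log(m)))
  g <- g / sum(g) * 1440
  expect_equal(unname(geometric_mean_composition(comps)), unname(g),
    tolerance = 1e-10
  )
  expect_error(geometric_mean_composition(m[0, ]), "empty")
})

test_that("standardize_week weights weekdays 5/7 and weekends 2/7 with fallback", {
  # 7 identical days collapse to that day's closed composition
  days <- tibble::tibble(
    pid = 1, dow = 1:7,
    sleep_min = 400, inactivity_min = 700, light_min = 220, mvpa_min = 120
  )
  out <- standardize_week(days)
  expect_composition_equal(out, close_composition(c(400, 700, 220, 120)))
  expect_false(out$dow_fallback)

  # hand arithmetic: sleep = (5/7)*400 + (2/7)*470 = 420 (sums already 1440)
  days2 <- tibble::tibble(
    pid = 2, dow = 1:7,
    sleep_min = c(rep(400, 5), rep(470, 2)),
    inactivity_min = c(rep(700, 5), rep(630, 2)),
    light_min = 200, mvpa_min = 140
  )
  out2 <- standardize_week(days2)
  expect_equal(out2$sleep_min, 420, tolerance = 1e-10)
  expect_equal(out2$inactivity_min, 680, tolerance = 1e-10)

  # weekdays only: weekday mean with the fallback flag set
  out3 <- standardize_week(days[days$dow <= 5, ])
  expect_true(out3$dow_fallback)
  expect_composition_equal(out3, close_composition(c(400, 700, 220, 120)))

  short_day <- days
  short_day$sleep_min[1] <- 0
  short_day$inactivity_min[1] <- 100
  short_day$light_min[1] <- 50
  short_day$mvpa_min[1] <- 20
  expect_error(standardize_week(short_day), "outside")
  expect_error(standardize_week(days[0, ]), "non-empty")
})

test_that("trim_extremes removes exactly the rows outside per-behavior percentiles", {
  comps <- random_compositions(1000, seed = 11)
  # identical compositions: nothing to trim
  same <- tibble::tibble(
    sleep_min = rep(400, 1000), inactivity_min = 700,
    light_min = 220, mvpa_min = 120
  )
  expect_equal(nrow(trim_extremes(same)), 1000)

  # plant one extreme MVPA value above everyone else: the sorting oracle
  # says exactly that row exceeds the 99.9th percentile
  planted <- comps
  planted$mvpa_min[500] <- max(planted$mvpa_min) * 10
  kept <- trim_extremes(planted)
  log <- trim_log(kept)
  expect_s3_class(log, "tbl_df")
  expect_true(nrow(kept) < 1000)
  expect_false(any(kept$mvpa_min == planted$mvpa_min[500]))

  # rows strictly inside every bound are never removed, and the union
  # bound caps the removal fraction at 0.8%
  comps2 <- dplyr::mutate(comps, pid = dplyr::row_number())
  m <- as.matrix(comps2[behavior_cols()])
  lo <- apply(m, 2, quantile, probs = 0.001, type = 7)
  hi <- apply(m, 2, quantile, probs = 0.999, type = 7)
  interior <- rowSums(sweep(m, 2, lo, "<=") | sweep(m, 2, hi, ">=")) == 0
  kept2 <- trim_extremes(comps2)
  expect_true(all(comps2$pid[interior] %in% kept2$pid))
  expect_lte(1000 - nrow(kept2), 0.008 * 1000)
})

test_that("sleep groups follow the 6/8/9-hour thresholds with overlap", {
  co <- tibble::tibble(
    sleep_min = c(355, 360, 390, 480, 510, 540, 560),
    inactivity_min = 700, light_min = 200, mvpa_min = 100
  )
  out <- assign_sleep_group(co)
  expect_equal(out$sleep_short, c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(out$sleep_normal, c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(out$sleep_long, c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  # no one with positive sleep is unlabelled
  expect_true(all(out$sleep_short | out$sleep_normal | out$sleep_long))
  expect_equal(
    subgroup_members(co, "normal"),
    out$sleep_normal
  )
})
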