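test_that("tallies combine day counts with matches attributed to the day-1 district", {
  d1 <- make_roster(4, district = "Chamkar Mon")
  d2 <- as_day2(make_roster(3, district = "Chamkar Mon"))
  ms <- match_rosters(d1, d2)
  counts <- day_counts(d1, d2)
  t <- tally_districts(ms, counts)
  expect_equal(t[t$district == "Chamkar Mon", c("c1", "c2", "m")],
               data.frame(c1 = 4L, c2 = 3L, m = 3L),
               ignore_attr = TRUE)

  # no matches -> M = 0 everywhere
  empty_ms <- match_rosters(d1, as_day2(make_roster(0)))
  t0 <- tally_districts(empty_ms, counts)
  expect_true(all(t0$m == 0))
})

test_that("full-capture noise-free districts tally as (n, n, n)", {
  cfg <- sim_config(seed = 67, n_per_district = c("Siem Reap" = 40),
                    p1 = 1, p2 = 1, duplicate_encounter_prob = 0,
                    name_noise_prob = 0)
  sim <- simulate_census(cfg)
  ms <- match_rosters(sim$day1, sim$day2)
  t <- tally_districts(ms, day_counts(sim$day1, sim$day2))
  expect_equal(unlist(t[1, c("c1", "c2", "m")], use.names = FALSE),
               c(40L, 40L, 40L))
})

test_that("the district estimator reproduces its defining arithmetic", {
  # half-up rounding case: 22 + 19 + 4 + 104.5 = 149.5 -> 150
  e <- estimate_district(22, 19, 4)
  expect_equal(e$T, 150)
  expect_equal(e$U, 104.5)
  # plain case
  expect_equal(estimate_district(55, 48, 5)$T, 636)
  # algebraic identity (n, n, n) -> U = n, T = 4n
  for (n in c(13, 40, 77)) {
    e <- estimate_district(n, n, n)
    expect_equal(e$U, n)
    expect_equal(e$T, 4 * n)
  }
})

test_that("the exclusion and zero-match rules produce explicit statuses", {
  expect_equal(estimate_district(10, 10, 5)$status, "excluded_small_counts")
  expect_equal(estimate_district(12, 12, 0)$status, "excluded_small_counts")
  e <- estimate_district(20, 20, 0)
  expect_equal(e$status, "undefined_zero_matches")
  expect_true(is.na(e$T))
  expect_error(estimate_district(-1, 5, 0), "negative")
  expect_error(estimate_district(5, 5, 6), "exceeds")
  # the exclusion threshold is configurable
  expect_equal(estimate_district(10, 10, 5, min_combined = 20)$status,
               "estimated")
})

test_that("Lincoln-Petersen and Chapman comparators match closed forms", {
  expect_equal(lincoln_petersen(55, 48, 5), 528)
  expect_equal(lincoln_petersen(24, 25, 1), 600)
  expect_equal(lincoln_petersen(7, 7, 7), 7)
  expect_error(lincoln_petersen(5, 5, 0), "M = 0")

  expect_equal(chapman(55, 48, 5)$estimate, 56 * 49 / 6 - 1)
  expect_equal(chapman(24, 25, 1)$estimate, 324)
  for (n in c(5, 20)) expect_equal(chapman(n, n, n)$estimate, n)
  # defined at M = 0, and the interval is truncated at the observed count
  ch <- chapman(10, 10, 0)
  expect_equal(ch$estimate, 120)
  expect_gte(ch$ci95[1], 20)
  expect_lte(ch$ci95[1], ch$ci95[2])
})

test_that("the unrounded total always exceeds Lincoln-Petersen by the observed records", {
  set.seed(101)
  for (i in 1:1000) {
    c1 <- sample(1:500, 1)
    c2 <- sample(1:500, 1)
    m <- sample(1:min(c1, c2), 1)
    e <- estimate_district(c1, c2, m, min_combined = 0)
    t_unrounded <- c1 + c2 + m + e$U
    expect_equal(t_unrounded, lincoln_petersen(c1, c2, m) + c1 + c2 + m,
                 tolerance = 1e-9)
  }
})

test_that("the total strictly decreases as matches increase", {
  T_at <- vapply(1:20, function(m) estimate_district(50, 40, m)$T, numeric(1))
  expect_true(all(diff(T_at) < 0))
})

test_that("the multiplier comes from the rounded total at two decimals", {
  expect_equal(estimate_district(19, 9, 5)$k, 3.53)   # 67 / 19
  expect_equal(estimate_district(24, 25, 1)$k, 27.08) # 650 / 24
  expect_equal(round_half_away(67.2 / 19, 2), 3.54)   # unrounded would differ
})

test_that("half-away-from-zero rounding differs from banker's rounding where it must", {
  expect_equal(round_half_away(149.5), 150)
  expect_equal(round_half_away(384.25), 384)
  expect_equal(round_half_away(-149.5), -150)
  expect_equal(round_half_away(2.125, 2), 2.13)
  expect_equal(round_half_away(0.5), 1)
})

test_that("aggregation sums estimated districts and ranges the multipliers", {
  t1 <- table1_tallies()
  est <- estimate_population(t1)
  agg <- aggregate_estimates(est)
  expect_equal(agg$c1, 282L)
  expect_equal(agg$c2, 221L)
  expect_equal(agg$m, 38L)
  expect_equal(agg$n_estimated, 9L)

  # excluded districts are reported, not summed
  t1$c2[t1$district == "Komrieng"] <- 5L  # c1 + c2 = 16 < 25
  est2 <- estimate_population(t1)
  agg2 <- aggregate_estimates(est2)
  expect_equal(agg2$excluded, "Komrieng")
  expect_equal(agg2$n_estimated, 8L)

  empty <- aggregate_estimates(est[0, ])
  expect_equal(empty$total, 0)
  expect_length(empty$k_range, 0)
})
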