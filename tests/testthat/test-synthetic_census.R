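test_that("configuration validation rejects degenerate inputs", {
  expect_error(sim_config(n_per_district = c("Doun Penh" = 0)), ">= 1")
  expect_error(sim_config(n_per_district = c("Nowhere" = 10)), "named")
  expect_error(sim_config(n_per_district = c("Doun Penh" = 10), p1 = 1.2),
               "probabilities")
  expect_error(sim_config(n_per_district = c("Doun Penh" = 10),
                          migration_out = 1), "migration")
  expect_error(sim_config(n_per_district = c("Doun Penh" = 10),
                          age_distribution = c("13" = 0.6, "14" = 0.6)),
               "sum to 1")
  expect_error(sim_config(n_per_district = c("Doun Penh" = 10),
                          age_distribution = c("12" = 1)), "13-17")
})

test_that("the age distribution is renormalised exactly to 1", {
  cfg <- sim_config(n_per_district = c("Doun Penh" = 10))
  expect_equal(sum(cfg$age_distribution), 1, tolerance = 1e-12)
})

test_that("generation is deterministic given the seed", {
  cfg <- sim_config(seed = 9, n_per_district = c("Doun Penh" = 80,
                                                 "Chamkar Mon" = 40),
                    p1 = 0.4, p2 = 0.4, name_noise_prob = 0.3)
  s1 <- simulate_census(cfg)
  s2 <- simulate_census(cfg)
  expect_identical(s1$day1, s2$day1)
  expect_identical(s1$day2, s2$day2)
  expect_identical(s1$true_matches, s2$true_matches)
  # byte-identical on disk as well
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_census_sim(s1, d1)
  write_census_sim(s2, d2)
  for (f in c("day1.csv", "day2.csv", "truth.csv", "true_matches.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("generated sex and age marginals match the configured distributions", {
  cfg <- sim_config(seed = 31, n_per_district = c("Doun Penh" = 10000))
  truth <- suppressWarnings(generate_population(cfg))
  p_male <- mean(truth$persons$sex == "male")
  se <- sqrt(0.6432 * (1 - 0.6432) / 10000)
  expect_lt(abs(p_male - 0.6432), 3 * se)
  expect_true(all(truth$persons$age %in% 13:17))
  p13 <- mean(truth$persons$age == 13L)
  se13 <- sqrt(0.3511 * (1 - 0.3511) / 10000)
  expect_lt(abs(p13 - cfg$age_distribution[["13"]]), 3 * se13)
})

test_that("certain capture yields C1 = C2 = M = N in every district", {
  cfg <- sim_config(seed = 2, n_per_district = c("Doun Penh" = 60,
                                                 "Siem Reap" = 45),
                    p1 = 1, p2 = 1, duplicate_encounter_prob = 0,
                    name_noise_prob = 0)
  sim <- simulate_census(cfg)
  counts <- day_counts(sim$day1, sim$day2)
  for (d in c("Doun Penh", "Siem Reap")) {
    n <- cfg$n_per_district[[d]]
    expect_equal(counts$count[counts$district == d & counts$day == 1], n)
    expect_equal(counts$count[counts$district == d & counts$day == 2], n)
  }
  expect_equal(nrow(sim$true_matches), 105L)
})

test_that("a zero day-2 capture probability empties the second roster", {
  cfg <- sim_config(seed = 3, n_per_district = c("Doun Penh" = 50),
                    p1 = 1, p2 = 0)
  sim <- simulate_census(cfg)
  expect_equal(nrow(sim$day2), 0L)
  expect_equal(nrow(sim$true_matches), 0L)
})

test_that("realized counts have binomial spread around N * p", {
  cfg <- sim_config(seed = 7, n_per_district = c("Doun Penh" = 500),
                    p1 = 0.3, p2 = 0.3, duplicate_encounter_prob = 0)
  sim <- simulate_census(cfg)
  c1 <- nrow(sim$day1)
  expect_lt(abs(c1 - 150), 3 * sqrt(500 * 0.3 * 0.7))
})

test_that("with independent lists the day-2 recapture rate estimates day-1 coverage", {
  # M / C2 is a consistent estimate of p1 = C1 / N when delta = 0
  cfg <- sim_config(seed = 13, n_per_district = c("Doun Penh" = 12000),
                    p1 = 0.3, p2 = 0.25, duplicate_encounter_prob = 0)
  truth <- suppressWarnings(generate_population(cfg))
  sim <- simulate_counts(truth, cfg)
  ch <- sim$capture_history
  m <- sum(ch$captured_day1 & ch$captured_day2)
  c2 <- sum(ch$captured_day2)
  c1 <- sum(ch$captured_day1)
  expect_lt(abs(m / c2 - c1 / 12000), 3 * sqrt(0.3 * 0.7 / c2))
})

test_that("every record maps to a person and true pairs equal dual captures", {
  cfg <- sim_config(seed = 17, n_per_district = c("Doun Penh" = 300),
                    p1 = 0.5, p2 = 0.5, duplicate_encounter_prob = 0.2,
                    name_noise_prob = 0.2)
  sim <- simulate_census(cfg)
  expect_true(all(sim$record_map$person_id %in% sim$truth$persons$person_id))
  expect_setequal(sim$record_map$record_id,
                  c(sim$day1$record_id, sim$day2$record_id))
  both <- sum(sim$capture_history$captured_day1 &
                sim$capture_history$captured_day2)
  expect_equal(nrow(sim$true_matches), both)
})

test_that("transliteration noise only substitutes listed bank variants", {
  bank <- load_name_bank()
  legal_given <- c(bank$name[bank$type == "given"],
                   unlist(bank$variants[bank$type == "given"]))
  legal_family <- c(bank$name[bank$type == "family"],
                    unlist(bank$variants[bank$type == "family"]))
  cfg <- sim_config(seed = 23, n_per_district = c("Doun Penh" = 200),
                    p1 = 0.8, p2 = 0.8, name_noise_prob = 1)
  sim <- simulate_census(cfg)
  for (roster in list(sim$day1, sim$day2)) {
    expect_true(all(roster$given_name %in% legal_given))
    expect_true(all(roster$family_name %in% legal_family))
    nick <- roster$nickname[!is.na(roster$nickname)]
    expect_true(all(nick %in% legal_given))
  }
  # noise really changed spellings somewhere
  map <- stats::setNames(sim$truth$persons$given_name,
                         sim$truth$persons$person_id)
  canon <- unname(map[sim$record_map$person_id[sim$record_map$day == 1]])
  expect_gt(sum(sim$day1$given_name != canon), 0)
})

test_that("out-migration removes persons from the day-2 risk set and in-migrants are new", {
  cfg <- sim_config(seed = 29, n_per_district = c("Doun Penh" = 400),
                    p1 = 0.5, p2 = 0.5, migration_out = 0.3,
                    migration_in = 0.2, duplicate_encounter_prob = 0)
  truth <- generate_population(cfg)
  sim <- simulate_counts(truth, cfg)
  ch <- sim$capture_history
  expect_false(any(ch$captured_day2 & ch$migrated_out))
  # day-2 roster contains persons outside the original truth (in-migrants)
  d2_persons <- sim$record_map$person_id[sim$record_map$day == 2]
  expect_gt(length(setdiff(d2_persons, truth$persons$person_id)), 0)
  # in-migrants never appear as true matches
  expect_true(all(sim$true_matches$person_id %in% truth$persons$person_id))
})

test_that("list dependence shifts the day-2 capture rate of day-1 captures", {
  cfg <- sim_config(seed = 37, n_per_district = c("Doun Penh" = 20000),
                    p1 = 0.4, p2 = 0.3, delta = 1,
                    duplicate_encounter_prob = 0)
  truth <- suppressWarnings(generate_population(cfg))
  sim <- simulate_counts(truth, cfg)
  ch <- sim$capture_history
  p2_in <- mean(ch$captured_day2[ch$captured_day1])
  p2_out <- mean(ch$captured_day2[!ch$captured_day1])
  expect_gt(p2_in, p2_out + 0.1)
  expect_lt(abs(p2_in - stats::plogis(stats::qlogis(0.3) + 1)), 0.03)
})
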