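test_that("field similarities behave per definition", {
  a <- make_roster(1)[1, ]
  cmp <- field_similarity(a, a)
  expect_true(all(cmp$similarity[cmp$available] == 1))
  expect_false(cmp$available[cmp$field == "nickname"])

  b <- a
  b$sex <- if (a$sex == "male") "female" else "male"
  cmp <- field_similarity(a, b)
  expect_equal(cmp$similarity[cmp$field == "sex"], 0)
  expect_equal(cmp$similarity[cmp$field == "given_name"], 1)

  b <- a
  a$age <- 14L; b$age <- 15L
  expect_equal(field_similarity(a, b)$similarity[cmp$field == "age"], 0.5)
  a$age <- 13L; b$age <- 17L
  expect_equal(field_similarity(a, b)$similarity[cmp$field == "age"], 0)
})

test_that("the linkage weight is the distinctiveness-weighted mean over available fields", {
  a <- make_roster(1)[1, ]
  w1 <- link_weight(field_similarity(a, a))
  expect_equal(w1$weight, 1)

  cmp <- data.frame(field = c("given_name", "family_name"),
                    similarity = c(0.9, 0.6), available = c(TRUE, TRUE),
                    stringsAsFactors = FALSE)
  w <- link_weight(cmp, c(given_name = 2, family_name = 1))
  expect_equal(w$weight, (2 * 0.9 + 1 * 0.6) / 3)

  cmp$similarity <- c(0, 0)
  expect_equal(link_weight(cmp, c(given_name = 2, family_name = 1))$weight, 0)

  one <- data.frame(field = "given_name", similarity = 1, available = TRUE,
                    stringsAsFactors = FALSE)
  expect_true(is.na(link_weight(one, c(given_name = 2))$weight))
})

test_that("phonetic keys collapse transliteration variants", {
  expect_equal(phonetic_key(""), "")
  expect_equal(phonetic_key(NA_character_), "")
  expect_equal(phonetic_key("Chan"), phonetic_key("Chann"))
  expect_equal(phonetic_key("Phalla"), "PL")
  expect_equal(phonetic_key("Sok"), phonetic_key("Sokh"))
  expect_equal(phonetic_key("Thida"), phonetic_key("Tida"))
  # every packaged variant group shares at most a few distinct keys and
  # never collides with another canonical name of the same type
  bank <- load_name_bank()
  for (ty in c("given", "family")) {
    b <- bank[bank$type == ty, ]
    expect_false(anyDuplicated(phonetic_key(b$name)) > 0)
  }
})

test_that("an exact day-2 copy is fully matched in the auto tier", {
  d1 <- make_roster(10)
  d2 <- as_day2(d1)
  ms <- match_rosters(d1, d2)
  expect_equal(nrow(ms$pairs), 10L)
  expect_true(all(ms$pairs$tier == "auto"))
  expect_true(all(ms$pairs$weight == 1))
  expect_equal(sub("d2", "d1", ms$pairs$day2_record_id),
               ms$pairs$day1_record_id)
  expect_length(ms$unmatched_day1, 0)
})

test_that("disjoint populations with distinct identities yield zero matches", {
  d1 <- make_roster(5)
  d2 <- as_day2(make_roster(5))
  d2$given_name <- c("Makara", "Oudom", "Tevy", "Socheat", "Leakhena")
  d2$family_name <- c("Svay", "Nuon", "Khiev", "Duong", "Hok")
  d2$father_name <- "Vireak"; d2$mother_name <- "Chariya"
  d2$sex <- rev(d2$sex)
  d2$province_origin <- "Kratie"
  ms <- match_rosters(d1, d2)
  expect_equal(nrow(ms$pairs), 0L)
  expect_length(ms$unmatched_day2, 5)
})

test_that("assignment is one-to-one and weights lie in [0, 1]", {
  cfg <- sim_config(seed = 53, n_per_district = c("Chamkar Mon" = 150,
                                                  "Doun Penh" = 150),
                    p1 = 0.5, p2 = 0.5, name_noise_prob = 0.3)
  sim <- simulate_census(cfg)
  ms <- match_rosters(dedup_within_day(sim$day1)$retained,
                      dedup_within_day(sim$day2)$retained)
  expect_equal(anyDuplicated(ms$pairs$day1_record_id), 0L)
  expect_equal(anyDuplicated(ms$pairs$day2_record_id), 0L)
  expect_true(all(ms$pairs$weight >= 0 & ms$pairs$weight <= 1))
})

test_that("swapping the roster arguments yields the same pair set", {
  cfg <- sim_config(seed = 59, n_per_district = c("Chamkar Mon" = 120),
                    p1 = 0.5, p2 = 0.5, name_noise_prob = 0.25)
  sim <- simulate_census(cfg)
  r1 <- dedup_within_day(sim$day1)$retained
  r2 <- dedup_within_day(sim$day2)$retained
  ms_ab <- match_rosters(r1, r2)
  ms_ba <- match_rosters(r2, r1)
  key <- function(ms) sort(paste(ms$pairs$day1_record_id,
                                 ms$pairs$day2_record_id))
  expect_identical(key(ms_ab), key(ms_ba))
})

test_that("raising the threshold never increases the auto-tier match count", {
  cfg <- sim_config(seed = 61, n_per_district = c("Doun Penh" = 200),
                    p1 = 0.5, p2 = 0.5, name_noise_prob = 0.3)
  sim <- simulate_census(cfg)
  r1 <- dedup_within_day(sim$day1)$retained
  r2 <- dedup_within_day(sim$day2)$retained
  n_auto <- vapply(c(0.7, 0.8, 0.9, 0.99), function(th) {
    sum(match_rosters(r1, r2, threshold = th)$pairs$tier == "auto")
  }, numeric(1))
  expect_true(all(diff(n_auto) <= 0))
})

test_that("candidate pairs are blocked to the same city and nearby districts", {
  geo <- toy_geography()
  base <- make_roster(1, district = "A", city = "X")
  d2 <- as_day2(base)
  # same person re-encountered in nearby district B: matched
  d2$district <- "B"
  ms <- match_rosters(base, d2, geo)
  expect_equal(nrow(ms$pairs), 1L)
  # non-adjacent district C in the same city: not a candidate
  d2$district <- "C"
  expect_equal(nrow(match_rosters(base, d2, geo)$pairs), 0L)
  # another city entirely: never matched
  d2$district <- "D"; d2$city <- "Y"
  expect_equal(nrow(match_rosters(base, d2, geo)$pairs), 0L)
})

test_that("cartoon recall rescues heavily noised true pairs", {
  d1 <- make_roster(4)
  d2 <- as_day2(d1)
  # obliterate both names of record 2: the weight falls below the review
  # floor (no phonetic rescue either) but stays above the recall floor
  d2$given_name[2] <- "Xuxuxu"
  d2$family_name[2] <- "Zzz"
  ms0 <- match_rosters(d1, d2)
  expect_false(d2$record_id[2] %in% ms0$pairs$day2_record_id)
  d2$recalled_prev_cartoon[2] <- TRUE
  ms1 <- match_rosters(d1, d2)
  i <- which(ms1$pairs$day2_record_id == d2$record_id[2])
  expect_length(i, 1L)
  expect_equal(ms1$pairs$tier[i], "recall")
  expect_equal(ms1$pairs$day1_record_id[i], d1$record_id[2])
})

test_that("the phonetic tier recovers spelling-variant pairs below the threshold", {
  d1 <- make_roster(1)
  d1$given_name <- "Phally"; d1$family_name <- "Sok"
  d1$nickname <- "Chan"; d1$father_name <- "Veasna"
  d1$mother_name <- "Srey"; d1$province_origin <- "Phnom Penh"
  d2 <- as_day2(d1)
  d2$given_name <- "Phaly"; d2$family_name <- "Sokh"
  d2$nickname <- "Chhan"; d2$father_name <- "Visna"
  d2$mother_name <- "Sray"; d2$province_origin <- "Kandal"
  w <- link_weight(field_similarity(d1[1, ], d2[1, ]))$weight
  expect_lt(w, 0.80)
  expect_gte(w, 0.60)
  ms <- match_rosters(d1, d2)
  expect_equal(nrow(ms$pairs), 1L)
  expect_equal(ms$pairs$tier, "phonetic")
})
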