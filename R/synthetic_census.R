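# Synthetic two-day street-census generator: hidden per-district
# populations with per-day capture probabilities, optional list dependence
# and between-day migration, same-day duplicate encounters, transliteration
# noise on romanized names, and imperfect cartoon recall — plus the ground
# truth needed to score deduplication, linkage and estimation.

PROVINCES <- c(
  "Phnom Penh", "Kandal", "Kampong Cham", "Battambang", "Siem Reap",
  "Banteay Meanchey", "Prey Veng", "Takeo", "Kampot", "Svay Rieng",
  "Kampong Speu", "Kampong Thom", "Pursat", "Kratie", "Preah Sihanouk"
)

CITY_PROVINCE <- c(
  "Poipet" = "Banteay Meanchey", "Battambang" = "Battambang",
  "Kampong Cham" = "Kampong Cham", "Phnom Penh" = "Phnom Penh",
  "Preah Sihanouk" = "Preah Sihanouk", "Siem Reap" = "Siem Reap"
)

# Characteristic-field marginals used by the generator. Shapes follow the
# published all-respondents column; missingness rates are the published
# per-variable missing counts out of 569 interviews.
CHARACTERISTIC_SPEC <- list(
  caregiver = list(type = "cat", missing = 6 / 569,
                   p = c(parent = 0.8366, family_member = 0.0959,
                         acquaintance = 0.0195, employer = 0.0053,
                         other = 0.0124, no_adult_caregiver = 0.0302)),
  school_attendance = list(type = "cat", missing = 6 / 569,
                           p = c(every_day = 0.4973, few_days_week = 0.0959,
                                 once_in_a_while = 0.0302, never = 0.3766)),
  literacy = list(type = "cat", missing = 44 / 569,
                  p = c(whole_sentence = 0.3219, parts_of_sentence = 0.3371,
                        cannot_read = 0.3333, other = 0.0019,
                        dont_know = 0.0057)),
  work_heavy = list(type = "lgl", missing = 48 / 569, p = 0.2975),
  chores_heavy = list(type = "lgl", missing = 54 / 569, p = 0.0660),
  interfere_school = list(type = "cat", missing = 72 / 569,
                          p = c(always = 0.0825, sometimes = 0.1690,
                                never = 0.6841, dont_know = 0.0644)),
  interfere_sleep = list(type = "cat", missing = 44 / 569,
                         p = c(always = 0.0800, sometimes = 0.2343,
                               never = 0.6705, dont_know = 0.0152)),
  injured_30d = list(type = "lgl", missing = 44 / 569, p = 0.1314),
  sick_30d = list(type = "lgl", missing = 44 / 569, p = 0.2914),
  safety = list(type = "cat", missing = 44 / 569,
                p = c(very_safe = 0.4457, somewhat_safe = 0.4419,
                      not_at_all_safe = 0.1048, dont_know = 0.0076)),
  trust = list(type = "cat", missing = 0,
               p = c(a_lot = 0.4857, somewhat = 0.4114,
                     not_at_all = 0.0838, dont_know = 0.0190))
)

#' Load the packaged romanized name bank
#'
#' Reads the packaged bank of romanized Khmer-style given and family
#' names. Each canonical name lists at least two hand-curated spelling
#' variants; transliteration noise in the generator substitutes one of
#' these variants, emulating how the same spoken name is transcribed
#' differently by different enumerators (never random character edits).
#'
#' @param path Optional path to an alternative bank CSV with columns
#'   `name`, `type` (given/family), `variants` (pipe-separated).
#' @return Data.frame with columns `name`, `type`, `variants` (list
#'   column of character vectors).
#' @export
load_name_bank <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "name_bank.csv",
                        package = "streetcensus", mustWork = TRUE)
  }
  bank <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "type", "variants") %in% names(bank)))
  if (nrow(bank) == 0L) {
    stop("name bank configuration error: empty bank", call. = FALSE)
  }
  bank$variants <- strsplit(bank$variants, "|", fixed = TRUE)
  n_var <- lengths(bank$variants)
  if (any(n_var < 2L)) {
    stop("name bank configuration error: every canonical name needs >= 2 ",
         "variants; offending: ",
         paste(bank$name[n_var < 2L], collapse = ", "), call. = FALSE)
  }
  bank
}

#' Simulation configuration for the synthetic census
#'
#' Bundles and validates every knob of the generator. The defaults encode
#' the study conditions: per-district population sizes equal to the
#' published capture-recapture totals, day-wise capture probabilities at
#' the overall observed coverage of each count (C1/T = 0.105,
#' C2/T = 0.082), independent lists (`delta = 0`), a closed population
#' (no migration — informants reported short-term movement was low), and
#' sex/age marginals from the published respondent table.
#'
#' @param seed Integer RNG seed (< 2^31 - 2).
#' @param n_per_district Named positive integer vector: true hidden
#'   population per district. Names must be districts of `geo`.
#' @param p1,p2 Day-1 / day-2 capture probabilities in [0, 1] (0 makes a
#'   count empty; useful for degenerate scenarios).
#' @param delta List-dependence parameter: log-odds shift of day-2
#'   capture for persons captured on day 1 (0 = independent lists).
#' @param migration_out,migration_in Proportions in [0, 1): share of the
#'   initial population leaving after day 1, and share (of each
#'   district's initial size) arriving as fresh identities before day 2.
#' @param duplicate_encounter_prob Probability a captured person is
#'   approached a second time the same day.
#' @param name_noise_prob Per-record, per-name-field probability that the
#'   canonical spelling is replaced by a transliteration variant.
#' @param recall_prob Probability a both-days-captured person correctly
#'   recalls the day-1 cartoon on day 2.
#' @param cartoon_honesty Probability a same-day re-encountered person
#'   reports having already been shown today's cartoon.
#' @param sex_p_male Proportion male (default 0.6432).
#' @param age_distribution Named probabilities over ages 13-17; must sum
#'   to 1 within 0.01 and is renormalised exactly.
#' @param geo A [geography()] (default [default_geography()]).
#' @return Validated config object of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       n_per_district = NULL,
                       p1 = 0.105, p2 = 0.082,
                       delta = 0,
                       migration_out = 0, migration_in = 0,
                       duplicate_encounter_prob = 0.05,
                       name_noise_prob = 0.15,
                       recall_prob = 0.7,
                       cartoon_honesty = 0.9,
                       sex_p_male = 0.6432,
                       age_distribution = c("13" = 0.3511, "14" = 0.2287,
                                            "15" = 0.2181, "16" = 0.1011,
                                            "17" = 0.1011),
                       geo = default_geography()) {
  stopifnot(inherits(geo, "geography"))
  seed <- as.integer(seed)
  stopifnot(length(seed) == 1L, !is.na(seed), abs(seed) < 2^31 - 2)
  if (is.null(n_per_district)) {
    t1 <- table1_tallies()
    est <- estimate_population(new_tally(t1$district, t1$c1, t1$c2, t1$m))
    n_per_district <- stats::setNames(as.integer(est$T), est$district)
  }
  if (is.null(names(n_per_district)) ||
      !all(names(n_per_district) %in% geo$districts$district)) {
    stop("sim_config error: n_per_district must be named by districts of ",
         "the geography", call. = FALSE)
  }
  n_per_district <- stats::setNames(as.integer(round(n_per_district)),
                                    names(n_per_district))
  if (any(n_per_district < 1L)) {
    stop("sim_config error: every district population must be >= 1",
         call. = FALSE)
  }
  probs <- c(p1 = p1, p2 = p2, duplicate = duplicate_encounter_prob,
             noise = name_noise_prob, recall = recall_prob,
             honesty = cartoon_honesty, male = sex_p_male)
  if (any(probs < 0 | probs > 1)) {
    stop("sim_config error: probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (migration_out < 0 || migration_out >= 1 ||
      migration_in < 0 || migration_in >= 1) {
    stop("sim_config error: migration proportions must lie in [0, 1)",
         call. = FALSE)
  }
  ages <- suppressWarnings(as.integer(names(age_distribution)))
  if (anyNA(ages) || !all(ages %in% 13:17) || any(age_distribution < 0)) {
    stop("sim_config error: age_distribution must be named by ages 13-17",
         call. = FALSE)
  }
  s <- sum(age_distribution)
  if (abs(s - 1) > 0.01) {
    stop("sim_config error: age_distribution must sum to 1 (within 0.01)",
         call. = FALSE)
  }
  age_distribution <- age_distribution / s
  structure(
    list(seed = seed, n_per_district = n_per_district, p1 = p1, p2 = p2,
         delta = delta, migration_out = migration_out,
         migration_in = migration_in,
         duplicate_encounter_prob = duplicate_encounter_prob,
         name_noise_prob = name_noise_prob, recall_prob = recall_prob,
         cartoon_honesty = cartoon_honesty, sex_p_male = sex_p_male,
         age_distribution = age_distribution, geo = geo),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic census config: N =", sum(x$n_per_district), "persons in",
      length(x$n_per_district), "district(s); p1 =", x$p1, ", p2 =", x$p2,
      ", delta =", x$delta, "\n")
  invisible(x)
}

# Draw n synthetic persons in one district, using the current RNG stream.
# Draw order (fixed, relied on for reproducibility): family, given,
# nickname, father, mother, sex, age, province, then each characteristic
# in CHARACTERISTIC_SPEC order (missingness first, then the value).
make_persons <- function(n, district, city, config, bank, id_offset) {
  given <- bank$name[bank$type == "given"]
  family <- bank$name[bank$type == "family"]
  nickname <- sample(given, n, replace = TRUE)
  has_nick <- stats::runif(n) < 0.5
  nickname[!has_nick] <- NA_character_
  persons <- data.frame(
    person_id = sprintf("p%06d", id_offset + seq_len(n)),
    family_name = sample(family, n, replace = TRUE),
    given_name = sample(given, n, replace = TRUE),
    nickname = nickname,
    father_name = sample(given, n, replace = TRUE),
    mother_name = sample(given, n, replace = TRUE),
    sex = ifelse(stats::runif(n) < config$sex_p_male, "male", "female"),
    age = sample(as.integer(names(config$age_distribution)), n,
                 replace = TRUE, prob = config$age_distribution),
    home_district = district,
    city = city,
    stringsAsFactors = FALSE
  )
  home_prov <- unname(CITY_PROVINCE[city])
  if (is.na(home_prov)) home_prov <- sample(PROVINCES, 1L)
  from_home <- stats::runif(n) < 0.5
  persons$province_origin <- ifelse(
    from_home, home_prov, sample(PROVINCES, n, replace = TRUE))
  for (v in names(CHARACTERISTIC_SPEC)) {
    spec <- CHARACTERISTIC_SPEC[[v]]
    is_missing <- stats::runif(n) < spec$missing
    if (spec$type == "cat") {
      val <- sample(names(spec$p), n, replace = TRUE,
                    prob = spec$p / sum(spec$p))
      val[is_missing] <- NA_character_
    } else {
      val <- stats::runif(n) < spec$p
      val[is_missing] <- NA
    }
    persons[[v]] <- val
  }
  persons
}

# Resample name draws until no two persons in the same city share both
# family and given name. Name-based linkage cannot distinguish true
# homonyms, so the generator keeps identities identifiable; without this
# the true match set would not be recoverable even in principle. When a
# city's population approaches the bank's combinatorial capacity the
# dedication is best-effort: remaining homonyms are reported by warning.
dedup_identities <- function(persons, given, family,
                             existing_key = character(0)) {
  tries <- 0L
  repeat {
    key <- paste(persons$city, persons$family_name, persons$given_name,
                 sep = "\r")
    dup <- duplicated(key) | key %in% existing_key
    if (!any(dup)) return(persons)
    tries <- tries + 1L
    if (tries > 40L) {
      warning("name bank capacity exceeded: ", sum(dup),
              " homonym identities remain in the population",
              call. = FALSE)
      return(persons)
    }
    persons$given_name[dup] <- sample(given, sum(dup), replace = TRUE)
    if (tries > 10L) {
      persons$family_name[dup] <- sample(family, sum(dup), replace = TRUE)
    }
  }
}

#' Generate a hidden synthetic population
#'
#' Draws the true (unobserved) population: exactly `n_per_district[d]`
#' persons per district, with canonical names from the packaged bank,
#' sex and age from the configured marginals, a home province, and
#' interview characteristics. Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return Object of class `"census_truth"`: list with `persons`
#'   (data.frame) and `true_n` (named vector of district sizes).
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  bank <- load_name_bank()
  districts <- names(config$n_per_district)
  cities <- district_city(config$geo, districts)
  offset <- 0L
  blocks <- vector("list", length(districts))
  for (i in seq_along(districts)) {
    n <- config$n_per_district[[i]]
    blocks[[i]] <- make_persons(n, districts[i], cities[i], config, bank,
                                offset)
    offset <- offset + n
  }
  persons <- do.call(rbind, blocks)
  rownames(persons) <- NULL
  persons <- dedup_identities(persons, bank$name[bank$type == "given"],
                              bank$name[bank$type == "family"])
  structure(list(persons = persons, true_n = config$n_per_district),
            class = "census_truth")
}

#' @export
print.census_truth <- function(x, ...) {
  cat("Synthetic truth:", nrow(x$persons), "persons across",
      length(x$true_n), "district(s)\n")
  invisible(x)
}

# Replace canonical name spellings by bank variants with probability
# `prob` per field entry (vectorised over records).
apply_name_noise <- function(values, variant_map, prob) {
  present <- !is.na(values) & nzchar(values)
  flip <- stats::runif(length(values)) < prob
  idx <- which(present & flip)
  if (length(idx) > 0L) {
    values[idx] <- vapply(values[idx], function(nm) {
      vars <- variant_map[[nm]]
      if (is.null(vars)) nm else sample(vars, 1L)
    }, character(1), USE.NAMES = FALSE)
  }
  values
}

# Build encounter records for one day from a persons block.
make_records <- function(persons, day, ids, noisy_names) {
  n <- nrow(persons)
  rec <- data.frame(
    record_id = ids,
    day = rep(as.integer(day), n),
    city = persons$city,
    district = persons$home_district,
    family_name = noisy_names$family_name,
    given_name = noisy_names$given_name,
    nickname = noisy_names$nickname,
    sex = persons$sex,
    age = persons$age,
    father_name = noisy_names$father_name,
    mother_name = noisy_names$mother_name,
    province_origin = persons$province_origin,
    saw_today_cartoon = noisy_names$saw_today_cartoon,
    recalled_prev_cartoon = noisy_names$recalled_prev_cartoon,
    stringsAsFactors = FALSE
  )
  for (v in names(CHARACTERISTIC_SPEC)) rec[[v]] <- persons[[v]]
  rec
}

#' Simulate the two count days over a synthetic population
#'
#' Runs the observation process: day-1 capture with probability `p1`;
#' day-2 capture with probability `plogis(qlogis(p2) + delta)` for day-1
#' captures and `p2` otherwise (list dependence); out-migrants leave
#' after day 1 and cannot be captured on day 2; in-migrants arrive as
#' fresh identities before day 2. Captured persons may be approached a
#' second time the same day (`duplicate_encounter_prob`), and the extra
#' encounter is flagged `saw_today_cartoon = TRUE` with probability
#' `cartoon_honesty`. Every emitted record carries independent
#' transliteration noise per name field; both-days captures get
#' `recalled_prev_cartoon = TRUE` with probability `recall_prob`.
#'
#' @param truth A [generate_population()] result from the same config.
#' @param config The same [sim_config()].
#' @return Object of class `"census_sim"`: list with `day1` and `day2`
#'   rosters, `true_matches` (day1/day2 record-id pairs of persons
#'   captured both days), `record_map` (record_id, person_id, day,
#'   district, is_duplicate), `capture_history` (per person), `truth`,
#'   and `config`.
#' @export
simulate_counts <- function(truth, config) {
  stopifnot(inherits(truth, "census_truth"), inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  bank <- load_name_bank()
  variant_map <- stats::setNames(bank$variants, bank$name)
  persons <- truth$persons
  n <- nrow(persons)

  # observation draws, in fixed order
  cap1 <- stats::runif(n) < config$p1
  out_mig <- stats::runif(n) < config$migration_out
  p2_eff <- stats::plogis(stats::qlogis(config$p2) + config$delta * cap1)
  cap2 <- (stats::runif(n) < p2_eff) & !out_mig

  # in-migrants: fresh identities present on day 2 only
  migrants <- NULL
  if (config$migration_in > 0) {
    districts <- names(config$n_per_district)
    cities <- district_city(config$geo, districts)
    n_in <- round(config$migration_in * config$n_per_district)
    blocks <- list()
    offset <- n
    for (i in seq_along(districts)) {
      if (n_in[[i]] > 0L) {
        blocks[[length(blocks) + 1L]] <-
          make_persons(n_in[[i]], districts[i], cities[i], config, bank,
                       offset)
        offset <- offset + n_in[[i]]
      }
    }
    if (length(blocks) > 0L) {
      migrants <- do.call(rbind, blocks)
      existing <- paste(persons$city, persons$family_name,
                        persons$given_name, sep = "\r")
      migrants <- dedup_identities(migrants,
                                   bank$name[bank$type == "given"],
                                   bank$name[bank$type == "family"],
                                   existing_key = existing)
      migrants_cap2 <- stats::runif(nrow(migrants)) < config$p2
      migrants <- migrants[migrants_cap2, , drop = FALSE]
    }
  }

  recall_ok <- cap1 & cap2 & (stats::runif(n) < config$recall_prob)

  emit_day <- function(day_persons, day, person_recalled, prefix) {
    m <- nrow(day_persons)
    if (m == 0L) {
      return(list(roster = empty_roster(),
                  map = data.frame(record_id = character(0),
                                   person_id = character(0),
                                   day = integer(0), district = character(0),
                                   is_duplicate = logical(0),
                                   stringsAsFactors = FALSE),
                  primary_ids = character(0)))
    }
    primary_ids <- sprintf("%s-%06d", prefix, seq_len(m))
    dup <- stats::runif(m) < config$duplicate_encounter_prob
    dup_honest <- stats::runif(m) < config$cartoon_honesty
    all_persons <- rbind(day_persons, day_persons[dup, , drop = FALSE])
    ids <- c(primary_ids, sprintf("%s-x%06d", prefix, which(dup)))
    saw <- c(rep(FALSE, m), dup_honest[dup])
    recalled <- c(person_recalled, person_recalled[dup])
    if (day == 1L) recalled <- rep(FALSE, length(recalled))
    noisy <- list(saw_today_cartoon = saw, recalled_prev_cartoon = recalled)
    for (fld in c("family_name", "given_name", "nickname",
                  "father_name", "mother_name")) {
      noisy[[fld]] <- apply_name_noise(all_persons[[fld]], variant_map,
                                       config$name_noise_prob)
    }
    roster <- make_records(all_persons, day, ids, noisy)
    list(
      roster = roster,
      map = data.frame(record_id = ids, person_id = all_persons$person_id,
                       day = rep(as.integer(day), length(ids)),
                       district = all_persons$home_district,
                       is_duplicate = c(rep(FALSE, m), rep(TRUE, sum(dup))),
                       stringsAsFactors = FALSE),
      primary_ids = primary_ids
    )
  }

  day1_persons <- persons[cap1, , drop = FALSE]
  d1 <- emit_day(day1_persons, 1L, rep(FALSE, nrow(day1_persons)), "d1")

  day2_persons <- persons[cap2, , drop = FALSE]
  day2_recalled <- recall_ok[cap2]
  if (!is.null(migrants) && nrow(migrants) > 0L) {
    day2_persons <- rbind(day2_persons, migrants)
    day2_recalled <- c(day2_recalled, rep(FALSE, nrow(migrants)))
  }
  d2 <- emit_day(day2_persons, 2L, day2_recalled, "d2")

  both <- persons$person_id[cap1 & cap2]
  p1_primary <- stats::setNames(d1$primary_ids, day1_persons$person_id)
  p2_primary <- stats::setNames(d2$primary_ids, day2_persons$person_id)
  true_matches <- data.frame(
    day1_record_id = unname(p1_primary[both]),
    day2_record_id = unname(p2_primary[both]),
    person_id = both,
    stringsAsFactors = FALSE
  )

  capture_history <- data.frame(
    person_id = persons$person_id,
    district = persons$home_district,
    captured_day1 = cap1, captured_day2 = cap2,
    migrated_out = out_mig,
    stringsAsFactors = FALSE
  )

  structure(
    list(day1 = d1$roster, day2 = d2$roster, true_matches = true_matches,
         record_map = rbind(d1$map, d2$map),
         capture_history = capture_history,
         truth = truth, config = config),
    class = "census_sim"
  )
}

#' @export
print.census_sim <- function(x, ...) {
  cat("Synthetic census:", nrow(x$day1), "day-1 and", nrow(x$day2),
      "day-2 encounter records;", nrow(x$true_matches),
      "true cross-day pair(s)\n")
  invisible(x)
}

#' Generate and observe a synthetic census in one call
#'
#' Convenience wrapper: [generate_population()] then [simulate_counts()].
#'
#' @param config A [sim_config()].
#' @return A `"census_sim"` (see [simulate_counts()]).
#' @export
simulate_census <- function(config) {
  simulate_counts(generate_population(config), config)
}

#' Capture-history tally without rosters
#'
#' Draws one closed-population capture history of size `N` (day-1 capture
#' probability `p1`; day-2 probability logistic-shifted by `delta` for
#' day-1 captures) and returns the observable triple under perfect
#' matching. Uses the current RNG stream; seed outside. Useful for
#' estimator-recovery simulations where the linkage stage is not under
#' study.
#'
#' @param n True population size.
#' @param p1,p2 Capture probabilities in [0, 1].
#' @param delta Log-odds list-dependence shift (default 0).
#' @return Named vector `c(c1, c2, m)`.
#' @export
simulate_capture_tally <- function(n, p1, p2, delta = 0) {
  stopifnot(n >= 1, p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1)
  cap1 <- stats::runif(n) < p1
  p2_eff <- stats::plogis(stats::qlogis(p2) + delta * cap1)
  cap2 <- stats::runif(n) < p2_eff
  c(c1 = sum(cap1), c2 = sum(cap2), m = sum(cap1 & cap2))
}

#' Write a synthetic census to disk
#'
#' Writes `day1.csv` and `day2.csv` in the roster interchange format plus
#' `truth.csv` (per-person capture history) and `true_matches.csv`
#' (day-1/day-2 record-id pairs).
#'
#' @param sim A [simulate_counts()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_census_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "census_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_roster(sim$day1, file.path(dir, "day1.csv"))
  write_roster(sim$day2, file.path(dir, "day2.csv"))
  utils::write.csv(sim$capture_history, file.path(dir, "truth.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(sim$true_matches, file.path(dir, "true_matches.csv"),
                   row.names = FALSE, na = "")
  invisible(dir)
}
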