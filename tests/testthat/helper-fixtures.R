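# Fixture builders shared across the suite. Rosters are built in code;
# nothing binary ships with the tests.

# A minimal valid roster of n records, all fields filled, no duplicates.
make_roster <- function(n, day = 1L, district = "Doun Penh",
                        city = "Phnom Penh", prefix = paste0("d", day)) {
  r <- empty_roster()
  if (n == 0L) return(r)
  given <- c("Sok", "Chan", "Dara", "Bopha", "Sophea", "Phally", "Vanna",
             "Kunthea", "Rith", "Veasna")
  family <- c("Chea", "Keo", "Lim", "Meas", "Ouk", "Phan", "Ros", "Seng",
              "Tan", "Var")
  idx <- seq_len(n)
  r <- data.frame(
    record_id = sprintf("%s-%04d", prefix, idx),
    day = rep(as.integer(day), n),
    city = city,
    district = district,
    family_name = family[(idx - 1L) %% 10L + 1L],
    given_name = given[(idx - 1L) %/% 10L %% 10L + 1L],
    nickname = NA_character_,
    sex = rep(c("male", "female"), length.out = n),
    age = 13L + (idx %% 5L),
    father_name = given[(idx + 3L) %% 10L + 1L],
    mother_name = given[(idx + 6L) %% 10L + 1L],
    province_origin = "Phnom Penh",
    saw_today_cartoon = FALSE,
    recalled_prev_cartoon = FALSE,
    stringsAsFactors = FALSE
  )
  for (v in characteristic_columns()) {
    r[[v]] <- if (v %in% c("work_heavy", "chores_heavy",
                           "injured_30d", "sick_30d")) NA else NA_character_
  }
  r[, roster_columns()]
}

# A small two-district geography for matching-blocking tests.
toy_geography <- function() {
  geography(
    data.frame(district = c("A", "B", "C", "D"),
               city = c("X", "X", "X", "Y"), stringsAsFactors = FALSE),
    data.frame(a = "A", b = "B", stringsAsFactors = FALSE)
  )
}

# Copy a roster to the other day (fresh ids, day flipped).
as_day2 <- function(roster) {
  roster$day <- rep(2L, nrow(roster))
  roster$record_id <- sub("^d1", "d2", roster$record_id)
  roster
}
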