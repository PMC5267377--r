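#' streetcensus: dual-system estimation for street-census rosters
#'
#' Implements a two-day (capture-recapture) street-census pipeline: synthetic
#' roster generation with ground truth, within-day deduplication via a
#' same-day cartoon rule, cross-day record linkage in three tiers, a
#' census-style population estimator with small-count exclusion and
#' corrective multipliers, and descriptive characteristic comparisons.
#'
#' @docType package
#' @name streetcensus-package
#' @keywords internal
"_PACKAGE"

# Fixed roster schema. Column order is the interchange contract: files are
# UTF-8 CSV with exactly these columns, booleans written "true"/"false",
# empty cell = missing.
ROSTER_ID_COLS <- c(
  "record_id", "day", "city", "district", "family_name", "given_name",
  "nickname", "sex", "age", "father_name", "mother_name", "province_origin",
  "saw_today_cartoon", "recalled_prev_cartoon"
)

CHARACTERISTIC_COLS <- c(
  "caregiver", "school_attendance", "literacy", "work_heavy", "chores_heavy",
  "interfere_school", "interfere_sleep", "injured_30d", "sick_30d",
  "safety", "trust"
)

LOGICAL_COLS <- c(
  "saw_today_cartoon", "recalled_prev_cartoon",
  "work_heavy", "chores_heavy", "injured_30d", "sick_30d"
)

#' Roster column names
#'
#' The fixed column set (and order) of an encounter roster: identifying
#' fields, district/day, cartoon flags, then the interview characteristic
#' fields. Every roster `data.frame` in the package carries exactly these
#' columns.
#'
#' @return Character vector of column names.
#' @export
roster_columns <- function() c(ROSTER_ID_COLS, CHARACTERISTIC_COLS)

#' Characteristic field names
#'
#' Names of the interview characteristic fields carried on a roster
#' (caregiver, school attendance, literacy, work and chore burden,
#' school/sleep interference, recent injury and illness, safety, trust).
#' Each is nullable: a missing value means the question was not answered.
#'
#' @return Character vector of column names.
#' @export
characteristic_columns <- function() CHARACTERISTIC_COLS

#' Construct an empty roster
#'
#' @return A zero-row data.frame with the full roster schema and column types.
#' @export
empty_roster <- function() {
  cols <- lapply(roster_columns(), function(cn) {
    if (cn %in% c("day", "age")) integer(0)
    else if (cn %in% LOGICAL_COLS) logical(0)
    else character(0)
  })
  names(cols) <- roster_columns()
  as.data.frame(cols, stringsAsFactors = FALSE)
}

blank_to_na <- function(x) {
  x[!is.na(x) & !nzchar(trimws(x))] <- NA_character_
  x
}

#' Validate a roster against the encounter-record invariants
#'
#' Checks the schema and the record-level invariants: unique `record_id`,
#' `day` in \{1, 2\}, `sex` in \{male, female\}, integer `age` in [13, 17],
#' non-empty `sex` and `district`, and `recalled_prev_cartoon` false on
#' day 1 (the recall question refers to the previous day's cartoon, which
#' only exists on day 2).
#'
#' @param roster A roster data.frame.
#' @return The roster, invisibly, if valid; otherwise an error is thrown
#'   naming the offending column or record_id.
#' @export
validate_roster <- function(roster) {
  stopifnot(is.data.frame(roster))
  missing_cols <- setdiff(roster_columns(), names(roster))
  if (length(missing_cols) > 0L) {
    stop("roster format error: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(roster) == 0L) return(invisible(roster))

  bad_record <- function(ok, what) {
    if (all(ok)) return(invisible(NULL))
    ids <- roster$record_id[!ok]
    stop("roster validation error: ", what, " for record_id ",
         paste(utils::head(ids, 5L), collapse = ", "),
         if (sum(!ok) > 5L) sprintf(" (and %d more)", sum(!ok) - 5L) else "",
         call. = FALSE)
  }

  if (anyNA(roster$record_id) || any(!nzchar(roster$record_id))) {
    stop("roster validation error: empty record_id", call. = FALSE)
  }
  if (anyDuplicated(roster$record_id)) {
    dup <- roster$record_id[duplicated(roster$record_id)]
    stop("roster validation error: duplicate record_id ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  bad_record(!is.na(roster$day) & roster$day %in% c(1L, 2L),
             "day not in {1, 2}")
  bad_record(!is.na(roster$sex) & roster$sex %in% c("male", "female"),
             "sex not in {male, female}")
  bad_record(!is.na(roster$age) & roster$age >= 13L & roster$age <= 17L &
               roster$age == as.integer(roster$age),
             "age outside [13, 17]")
  bad_record(!is.na(roster$district) & nzchar(roster$district),
             "empty district")
  bad_record(!is.na(roster$saw_today_cartoon), "missing saw_today_cartoon")
  recalled <- !is.na(roster$recalled_prev_cartoon) & roster$recalled_prev_cartoon
  bad_record(!(roster$day == 1L & recalled),
             "recalled_prev_cartoon true on day 1")
  invisible(roster)
}

#' Read an encounter roster from CSV
#'
#' Reads a roster file in the fixed interchange format (see
#' [roster_columns()]): UTF-8, comma-delimited, header row, booleans
#' "true"/"false", empty cells for missing values. Rows violating the
#' record invariants are rejected with an error naming the record — they
#' are never silently coerced.
#'
#' @param path Path to a roster CSV.
#' @param day_filter Optional day (1 or 2); if given, only that day's
#'   records are returned (after validating the whole file).
#' @return A validated roster data.frame.
#' @export
read_roster <- function(path, day_filter = NULL) {
  if (!file.exists(path)) stop("roster file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE, encoding = "UTF-8")
  missing_cols <- setdiff(roster_columns(), names(raw))
  if (length(missing_cols) > 0L) {
    stop("roster format error: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw <- raw[, roster_columns(), drop = FALSE]
  for (cn in names(raw)) raw[[cn]] <- blank_to_na(raw[[cn]])

  parse_int <- function(x, col) {
    out <- suppressWarnings(as.integer(x))
    bad <- !is.na(x) & is.na(out)
    if (any(bad)) {
      stop("roster validation error: non-integer ", col, " for record_id ",
           paste(raw$record_id[bad], collapse = ", "), call. = FALSE)
    }
    out
  }
  parse_lgl <- function(x, col) {
    out <- rep(NA, length(x))
    out[!is.na(x) & tolower(x) == "true"] <- TRUE
    out[!is.na(x) & tolower(x) == "false"] <- FALSE
    bad <- !is.na(x) & is.na(out)
    if (any(bad)) {
      stop("roster validation error: non-boolean ", col, " for record_id ",
           paste(raw$record_id[bad], collapse = ", "), call. = FALSE)
    }
    out
  }

  roster <- raw
  roster$day <- parse_int(raw$day, "day")
  roster$age <- parse_int(raw$age, "age")
  for (cn in LOGICAL_COLS) roster[[cn]] <- parse_lgl(raw[[cn]], cn)
  # day-1 recall answers do not exist; a blank cell reads back as FALSE
  roster$recalled_prev_cartoon[roster$day == 1L &
                                 is.na(roster$recalled_prev_cartoon)] <- FALSE
  validate_roster(roster)
  if (!is.null(day_filter)) {
    stopifnot(day_filter %in% c(1L, 2L))
    roster <- roster[roster$day == day_filter, , drop = FALSE]
    rownames(roster) <- NULL
  }
  roster
}

#' Write an encounter roster to CSV
#'
#' Inverse of [read_roster()]: booleans become "true"/"false", missing
#' values become empty cells, columns appear in the fixed interchange
#' order. `read_roster(write_roster(x))` returns `x` field-for-field.
#'
#' @param roster A valid roster data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_roster <- function(roster, path) {
  validate_roster(roster)
  out <- roster[, roster_columns(), drop = FALSE]
  for (cn in LOGICAL_COLS) {
    out[[cn]] <- ifelse(is.na(out[[cn]]), NA_character_,
                        ifelse(out[[cn]], "true", "false"))
  }
  # blank recall cells on day 1: the question is not asked there
  out$recalled_prev_cartoon[out$day == 1L] <- NA_character_
  utils::write.csv(out, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Define a study geography
#'
#' A geography is the set of enumerated districts (sangkats in Phnom Penh,
#' county-level districts elsewhere), each tagged with its city, plus a
#' symmetric "nearby" relation used to block candidate record pairs during
#' matching: linkage searches the same district and adjacent districts to
#' allow for short-range movement between the two count days.
#'
#' @param districts Data.frame with columns `district` and `city`.
#' @param adjacency Data.frame with columns `a` and `b`, each row one
#'   unordered nearby pair of distinct districts. Symmetry is implied;
#'   pairs are stored canonically.
#' @return An object of class `"geography"`.
#' @export
geography <- function(districts, adjacency = NULL) {
  stopifnot(is.data.frame(districts),
            all(c("district", "city") %in% names(districts)))
  if (anyDuplicated(districts$district)) {
    stop("geography error: duplicate district labels", call. = FALSE)
  }
  if (is.null(adjacency) || nrow(adjacency) == 0L) {
    adjacency <- data.frame(a = character(0), b = character(0),
                            stringsAsFactors = FALSE)
  }
  stopifnot(all(c("a", "b") %in% names(adjacency)))
  if (any(adjacency$a == adjacency$b)) {
    stop("geography error: adjacency must be irreflexive", call. = FALSE)
  }
  unknown <- setdiff(c(adjacency$a, adjacency$b), districts$district)
  if (length(unknown) > 0L) {
    stop("geography error: adjacency endpoint(s) not in districts: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  key <- paste(pmin(adjacency$a, adjacency$b), pmax(adjacency$a, adjacency$b),
               sep = "\r")
  adjacency <- adjacency[!duplicated(key), , drop = FALSE]
  structure(
    list(
      districts = districts[, c("district", "city"), drop = FALSE],
      adjacency = data.frame(a = pmin(adjacency$a, adjacency$b),
                             b = pmax(adjacency$a, adjacency$b),
                             stringsAsFactors = FALSE)
    ),
    class = "geography"
  )
}

#' @export
print.geography <- function(x, ...) {
  cat("Study geography:", nrow(x$districts), "districts in",
      length(unique(x$districts$city)), "cities;",
      nrow(x$adjacency), "nearby pair(s)\n")
  invisible(x)
}

#' Test whether two districts are the same or nearby
#'
#' @param geo A [geography()] object.
#' @param a,b District labels (vectorised, recycled).
#' @return Logical vector: `TRUE` where `a` and `b` are identical or form a
#'   nearby pair.
#' @export
districts_nearby <- function(geo, a, b) {
  stopifnot(inherits(geo, "geography"))
  key <- paste(pmin(a, b), pmax(a, b), sep = "\r")
  adj_key <- paste(geo$adjacency$a, geo$adjacency$b, sep = "\r")
  a == b | key %in% adj_key
}

#' District-to-city lookup
#'
#' @param geo A [geography()] object.
#' @param district District labels.
#' @return Character vector of city labels (NA for unknown districts).
#' @export
district_city <- function(geo, district) {
  stopifnot(inherits(geo, "geography"))
  geo$districts$city[match(district, geo$districts$district)]
}

#' Default study geography
#'
#' The nine enumerated districts of the two-day census, grouped by city,
#' with within-city sangkats marked mutually nearby. Used as the default
#' blocking geography for matching and as the simulation geography.
#'
#' @return A [geography()] object.
#' @export
default_geography <- function() {
  districts <- data.frame(
    district = c("Krong Poi Pet", "Battambang", "Komrieng", "Kampong Cham",
                 "Chamkar Mon", "Chbar Ampov", "Doun Penh",
                 "Preah Sihanouk", "Siem Reap"),
    city = c("Poipet", "Battambang", "Battambang", "Kampong Cham",
             "Phnom Penh", "Phnom Penh", "Phnom Penh",
             "Preah Sihanouk", "Siem Reap"),
    stringsAsFactors = FALSE
  )
  adjacency <- data.frame(
    a = c("Battambang", "Chamkar Mon", "Chamkar Mon", "Chbar Ampov"),
    b = c("Komrieng", "Chbar Ampov", "Doun Penh", "Doun Penh"),
    stringsAsFactors = FALSE
  )
  geography(districts, adjacency)
}
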