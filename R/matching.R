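# Cross-day record linkage: weighted field comparison with a threshold
# tier, a deterministic phonetic-review tier (stand-in for clerical review
# of spelling variants), and a cartoon-recall tier, restricted to nearby
# geography with greedy one-to-one assignment.

MATCH_FIELDS <- c("family_name", "given_name", "nickname", "sex", "age",
                  "father_name", "mother_name", "province_origin")

#' Default field distinctiveness weights
#'
#' Relative weight each comparison field contributes to the linkage
#' weight. Names differentiate individuals most, so given and family name
#' carry the largest weights; sex and province are weak (few levels).
#' All weights are configurable in [match_rosters()].
#'
#' @return Named numeric vector over the matching fields.
#' @export
default_distinctiveness <- function() {
  c(given_name = 3, family_name = 3, nickname = 1,
    father_name = 2, mother_name = 2, province_origin = 1,
    sex = 1, age = 2)
}

# Vectorised normalised Levenshtein similarity in [0, 1], case- and
# whitespace-insensitive, with caching over unique string pairs (rosters
# draw names from a finite bank, so pairs repeat heavily).
name_similarity <- function(a, b) {
  a1 <- tolower(trimws(as.character(a)))
  b1 <- tolower(trimws(as.character(b)))
  out <- rep(NA_real_, length(a1))
  avail <- !is.na(a1) & !is.na(b1) & nzchar(a1) & nzchar(b1)
  if (!any(avail)) return(out)
  key <- paste(a1[avail], b1[avail], sep = "\r")
  uk <- unique(key)
  parts <- strsplit(uk, "\r", fixed = TRUE)
  ua <- vapply(parts, `[`, character(1), 1L)
  ub <- vapply(parts, `[`, character(1), 2L)
  d <- vapply(seq_along(ua),
              function(i) utils::adist(ua[i], ub[i])[1L, 1L], numeric(1))
  sim <- 1 - d / pmax(nchar(ua), nchar(ub))
  out[avail] <- sim[match(key, uk)]
  out
}

exact_similarity <- function(a, b) {
  a1 <- tolower(trimws(as.character(a)))
  b1 <- tolower(trimws(as.character(b)))
  out <- rep(NA_real_, length(a1))
  avail <- !is.na(a1) & !is.na(b1) & nzchar(a1) & nzchar(b1)
  out[avail] <- as.numeric(a1[avail] == b1[avail])
  out
}

age_similarity <- function(a, b) {
  out <- rep(NA_real_, length(a))
  avail <- !is.na(a) & !is.na(b)
  out[avail] <- 1 - pmin(abs(a[avail] - b[avail]), 2) / 2
  out
}

# Similarity for every matching field over parallel record vectors;
# returns a list of numeric vectors (NA = field unavailable for the pair).
field_similarity_vec <- function(ra, rb) {
  list(
    family_name = name_similarity(ra$family_name, rb$family_name),
    given_name = name_similarity(ra$given_name, rb$given_name),
    nickname = name_similarity(ra$nickname, rb$nickname),
    sex = exact_similarity(ra$sex, rb$sex),
    age = age_similarity(ra$age, rb$age),
    father_name = name_similarity(ra$father_name, rb$father_name),
    mother_name = name_similarity(ra$mother_name, rb$mother_name),
    province_origin = exact_similarity(ra$province_origin, rb$province_origin)
  )
}

#' Field-by-field comparison of two encounter records
#'
#' Scores each matching variable of a record pair: name fields by
#' normalised edit-distance similarity, sex and province of origin by
#' exact agreement, age by 1 - min(|age difference|, 2)/2. A field is
#' unavailable (similarity NA) when missing on either side.
#'
#' @param a,b One-row roster data.frames (or lists with the roster fields).
#' @return Data.frame with columns `field`, `similarity`, `available`.
#' @export
field_similarity <- function(a, b) {
  a <- as.data.frame(as.list(a), stringsAsFactors = FALSE)
  b <- as.data.frame(as.list(b), stringsAsFactors = FALSE)
  sims <- field_similarity_vec(a, b)
  s <- vapply(MATCH_FIELDS, function(f) sims[[f]][1L], numeric(1))
  data.frame(field = MATCH_FIELDS, similarity = unname(s),
             available = !is.na(unname(s)), stringsAsFactors = FALSE)
}

#' Linkage weight from a field comparison
#'
#' The overall measure of agreement between two records: the
#' distinctiveness-weighted mean of the available field similarities,
#' w = sum(f_i s_i) / sum(f_i) over available fields i. Always in [0, 1];
#' 1 means every available field agrees exactly. Pairs with fewer than two
#' available fields are incomparable and signalled with an NA weight.
#'
#' @param cmp A comparison from [field_similarity()].
#' @param distinctiveness Named positive weights per field; defaults to
#'   [default_distinctiveness()].
#' @return List with `weight` (NA if incomparable), `n_available`, and
#'   `contributions` (per-field weighted share of the total).
#' @export
link_weight <- function(cmp, distinctiveness = default_distinctiveness()) {
  stopifnot(all(cmp$field %in% names(distinctiveness)),
            all(distinctiveness > 0))
  f <- distinctiveness[cmp$field]
  avail <- cmp$available
  if (sum(avail) < 2L) {
    return(list(weight = NA_real_, n_available = sum(avail),
                contributions = NULL))
  }
  denom <- sum(f[avail])
  contrib <- ifelse(avail, f * cmp$similarity / denom, NA_real_)
  list(weight = sum(contrib, na.rm = TRUE), n_available = sum(avail),
       contributions = stats::setNames(contrib, cmp$field))
}

#' Phonetic key for a romanized name
#'
#' A deterministic coarse phonetic encoding tuned to romanized Khmer
#' spelling variation: uppercase, map the aspirated digraphs PH/TH/KH/CH
#' to P/T/K/C, drop an H that follows a consonant, collapse runs of
#' repeated letters, then drop all vowels (A, E, I, O, U, Y) except a
#' leading one. Spelling variants of the same name ("Chan"/"Chann",
#' "Sok"/"Sokh") collapse to the same key.
#'
#' @param name Character vector of romanized names.
#' @return Character vector of keys ("" for empty/missing input).
#' @export
phonetic_key <- function(name) {
  vapply(as.character(name), function(nm) {
    if (is.na(nm)) return("")
    x <- toupper(gsub("[^A-Za-z]", "", nm))
    if (!nzchar(x)) return("")
    x <- gsub("PH", "P", x, fixed = TRUE)
    x <- gsub("TH", "T", x, fixed = TRUE)
    x <- gsub("KH", "K", x, fixed = TRUE)
    x <- gsub("CH", "C", x, fixed = TRUE)
    x <- gsub("(?<=[^AEIOUY])H", "", x, perl = TRUE)
    x <- gsub("(.)\\1+", "\\1", x)
    paste0(substr(x, 1L, 1L),
           gsub("[AEIOUY]", "", substr(x, 2L, nchar(x))))
  }, character(1), USE.NAMES = FALSE)
}

# Greedy one-to-one assignment by descending weight with a deterministic,
# label-symmetric tie-break (the unordered record_id pair).
greedy_one_to_one <- function(cand) {
  if (nrow(cand) == 0L) return(cand)
  lo <- pmin(cand$id1, cand$id2)
  hi <- pmax(cand$id1, cand$id2)
  cand <- cand[order(-cand$weight, lo, hi), , drop = FALSE]
  used1 <- new.env(hash = TRUE, parent = emptyenv())
  used2 <- new.env(hash = TRUE, parent = emptyenv())
  take <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    a <- cand$id1[i]
    b <- cand$id2[i]
    if (is.null(used1[[a]]) && is.null(used2[[b]])) {
      take[i] <- TRUE
      assign(a, TRUE, envir = used1)
      assign(b, TRUE, envir = used2)
    }
  }
  cand[take, , drop = FALSE]
}

# Candidate index pairs between two rosters, blocked on same city and
# same-or-nearby district. Returns a data.frame of row indices.
candidate_pairs <- function(r1, r2, geo) {
  d1 <- unique(r1$district)
  d2 <- unique(r2$district)
  grid <- expand.grid(da = d1, db = d2, stringsAsFactors = FALSE)
  same_city <- district_city(geo, grid$da) == district_city(geo, grid$db)
  same_city[is.na(same_city)] <- FALSE
  grid <- grid[same_city & districts_nearby(geo, grid$da, grid$db), ,
               drop = FALSE]
  if (nrow(grid) == 0L) {
    return(data.frame(i = integer(0), j = integer(0)))
  }
  blocks <- lapply(seq_len(nrow(grid)), function(g) {
    i <- which(r1$district == grid$da[g])
    j <- which(r2$district == grid$db[g])
    expand.grid(i = i, j = j)
  })
  do.call(rbind, blocks)
}

#' Match two deduplicated day rosters
#'
#' Links day-1 and day-2 records of the same individual in three tiers,
#' each one-to-one and applied in order:
#' \describe{
#'   \item{auto}{all candidate pairs with linkage weight >= `threshold`
#'     (default 0.80), assigned greedily by descending weight;}
#'   \item{phonetic}{remaining pairs with weight in
#'     [`review_floor`, `threshold`) whose given and family names share
#'     phonetic keys, with equal sex and age within 1 year — a
#'     deterministic stand-in for clerical review of spelling variants;}
#'   \item{recall}{still-unmatched day-2 records whose respondent
#'     correctly recalled the day-1 cartoon, paired with their best
#'     remaining day-1 candidate if its weight >= `recall_floor`.}
#' }
#' Candidate pairs are blocked to the same city and the same or nearby
#' district (per the geography) to allow for short-range movement between
#' days; pairs with fewer than two comparable fields are skipped.
#'
#' @param roster_a,roster_b Deduplicated single-day rosters (one per day;
#'   order of arguments does not matter — pairs are reported day-1 first).
#' @param geo A [geography()]; defaults to [default_geography()].
#' @param threshold Auto-accept weight threshold (default 0.80).
#' @param review_floor Lower weight bound for the phonetic tier (0.60).
#' @param recall_floor Minimum weight for the recall tier (0.50).
#' @param distinctiveness Field weights; see [default_distinctiveness()].
#' @return An object of class `"match_set"`: list with `pairs` (data.frame
#'   `day1_record_id`, `day2_record_id`, `day1_district`, `day2_district`,
#'   `weight`, `tier`), `unmatched_day1`, `unmatched_day2`,
#'   `n_candidates`, `n_incomparable`.
#' @export
match_rosters <- function(roster_a, roster_b, geo = default_geography(),
                          threshold = 0.80, review_floor = 0.60,
                          recall_floor = 0.50,
                          distinctiveness = default_distinctiveness()) {
  stopifnot(threshold > 0, threshold <= 1,
            review_floor >= 0, review_floor <= threshold,
            recall_floor >= 0, recall_floor <= 1)
  validate_roster(roster_a)
  validate_roster(roster_b)
  for (r in list(roster_a, roster_b)) {
    if (nrow(r) > 0L && length(unique(r$day)) != 1L) {
      stop("match precondition error: roster spans more than one day",
           call. = FALSE)
    }
  }
  # orient by the day field; fall back to argument order if tied
  day_a <- if (nrow(roster_a) > 0L) roster_a$day[1L] else 1L
  day_b <- if (nrow(roster_b) > 0L) roster_b$day[1L] else 2L
  if (day_a > day_b) {
    r1 <- roster_b
    r2 <- roster_a
  } else {
    r1 <- roster_a
    r2 <- roster_b
  }

  empty_pairs <- data.frame(
    day1_record_id = character(0), day2_record_id = character(0),
    day1_district = character(0), day2_district = character(0),
    weight = numeric(0), tier = character(0), stringsAsFactors = FALSE
  )
  finish <- function(pairs, n_candidates, n_incomparable) {
    structure(
      list(pairs = pairs,
           unmatched_day1 = setdiff(r1$record_id, pairs$day1_record_id),
           unmatched_day2 = setdiff(r2$record_id, pairs$day2_record_id),
           n_candidates = n_candidates, n_incomparable = n_incomparable),
      class = "match_set"
    )
  }
  if (nrow(r1) == 0L || nrow(r2) == 0L) {
    return(finish(empty_pairs, 0L, 0L))
  }

  idx <- candidate_pairs(r1, r2, geo)
  if (nrow(idx) == 0L) {
    return(finish(empty_pairs, 0L, 0L))
  }
  ra <- r1[idx$i, , drop = FALSE]
  rb <- r2[idx$j, , drop = FALSE]
  sims <- field_similarity_vec(ra, rb)
  f <- default_distinctiveness()
  f[names(distinctiveness)] <- distinctiveness
  f <- f[MATCH_FIELDS]
  num <- 0
  den <- 0
  n_avail <- 0L
  for (fd in MATCH_FIELDS) {
    s <- sims[[fd]]
    avail <- !is.na(s)
    num <- num + ifelse(avail, f[[fd]] * s, 0)
    den <- den + ifelse(avail, f[[fd]], 0)
    n_avail <- n_avail + avail
  }
  comparable <- n_avail >= 2L
  cand <- data.frame(
    id1 = ra$record_id, id2 = rb$record_id,
    d1 = ra$district, d2 = rb$district,
    weight = ifelse(comparable, num / pmax(den, .Machine$double.eps), NA_real_),
    sex1 = ra$sex, sex2 = rb$sex, age1 = ra$age, age2 = rb$age,
    g1 = ra$given_name, g2 = rb$given_name,
    f1 = ra$family_name, f2 = rb$family_name,
    recalled2 = !is.na(rb$recalled_prev_cartoon) & rb$recalled_prev_cartoon,
    stringsAsFactors = FALSE
  )
  n_incomparable <- sum(!comparable)
  cand <- cand[comparable, , drop = FALSE]

  taken <- empty_pairs
  add_tier <- function(taken, picked, tier) {
    if (nrow(picked) == 0L) return(taken)
    rbind(taken, data.frame(
      day1_record_id = picked$id1, day2_record_id = picked$id2,
      day1_district = picked$d1, day2_district = picked$d2,
      weight = picked$weight, tier = tier, stringsAsFactors = FALSE
    ))
  }
  remaining <- function(cand, taken) {
    cand[!(cand$id1 %in% taken$day1_record_id) &
           !(cand$id2 %in% taken$day2_record_id), , drop = FALSE]
  }

  # tier 1: threshold-weight linkage
  auto <- greedy_one_to_one(cand[cand$weight >= threshold, , drop = FALSE])
  taken <- add_tier(taken, auto, "auto")

  # tier 2: phonetic review of sub-threshold pairs
  rem <- remaining(cand, taken)
  if (nrow(rem) > 0L) {
    keys_g1 <- phonetic_key(rem$g1)
    keys_g2 <- phonetic_key(rem$g2)
    keys_f1 <- phonetic_key(rem$f1)
    keys_f2 <- phonetic_key(rem$f2)
    phon <- rem[
      rem$weight >= review_floor & rem$weight < threshold &
        nzchar(keys_g1) & keys_g1 == keys_g2 &
        nzchar(keys_f1) & keys_f1 == keys_f2 &
        rem$sex1 == rem$sex2 &
        !is.na(rem$age1) & !is.na(rem$age2) &
        abs(rem$age1 - rem$age2) <= 1, , drop = FALSE]
    taken <- add_tier(taken, greedy_one_to_one(phon), "phonetic")
  }

  # tier 3: cartoon-recall review
  rem <- remaining(cand, taken)
  if (nrow(rem) > 0L) {
    rec <- rem[rem$recalled2 & rem$weight >= recall_floor, , drop = FALSE]
    taken <- add_tier(taken, greedy_one_to_one(rec), "recall")
  }

  if (anyDuplicated(taken$day1_record_id) ||
      anyDuplicated(taken$day2_record_id)) {
    stop("internal error: one-to-one assignment violated", call. = FALSE)
  }
  rownames(taken) <- NULL
  finish(taken, nrow(idx), n_incomparable)
}

#' @export
print.match_set <- function(x, ...) {
  cat("Match set:", nrow(x$pairs), "pair(s)",
      sprintf("(auto %d, phonetic %d, recall %d);",
              sum(x$pairs$tier == "auto"),
              sum(x$pairs$tier == "phonetic"),
              sum(x$pairs$tier == "recall")),
      length(x$unmatched_day1), "day-1 and",
      length(x$unmatched_day2), "day-2 records unmatched\n")
  invisible(x)
}

#' Person-level precision and recall of a match set against ground truth
#'
#' Maps each linked record pair back to the generating persons and scores
#' the linkage: a predicted pair is correct when both records belong to
#' the same person; recall is taken over the true cross-day pairs.
#'
#' @param match_set A [match_rosters()] result.
#' @param sim A simulation from [simulate_counts()] (supplies the
#'   record-to-person map and the true match set).
#' @return List with `precision`, `recall`, `n_pred`, `n_true`,
#'   `n_correct`. Precision is NA when nothing was predicted; recall is
#'   NA when there are no true pairs.
#' @export
match_quality <- function(match_set, sim) {
  stopifnot(inherits(match_set, "match_set"), inherits(sim, "census_sim"))
  map <- stats::setNames(sim$record_map$person_id, sim$record_map$record_id)
  pairs <- match_set$pairs
  p1 <- unname(map[pairs$day1_record_id])
  p2 <- unname(map[pairs$day2_record_id])
  n_pred <- nrow(pairs)
  n_correct <- sum(!is.na(p1) & !is.na(p2) & p1 == p2)
  n_true <- nrow(sim$true_matches)
  list(
    precision = if (n_pred > 0L) n_correct / n_pred else NA_real_,
    recall = if (n_true > 0L) n_correct / n_true else NA_real_,
    n_pred = n_pred, n_true = n_true, n_correct = n_correct
  )
}
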