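#' Round half away from zero
#'
#' Commercial rounding: halves are rounded away from zero (149.5 -> 150,
#' -149.5 -> -150), unlike [base::round()]'s round-half-even. This is the
#' rounding used for reported totals and corrective multipliers.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

new_tally <- function(district, c1, c2, m) {
  if (any(c1 < 0 | c2 < 0 | m < 0)) {
    stop("tally validation error: negative counts", call. = FALSE)
  }
  if (any(m > pmin(c1, c2))) {
    stop("tally validation error: matches exceed min(C1, C2)", call. = FALSE)
  }
  data.frame(district = district, c1 = as.integer(c1), c2 = as.integer(c2),
             m = as.integer(m), stringsAsFactors = FALSE)
}

#' Per-district tallies from day counts and a match set
#'
#' Assembles the (Count 1, Count 2, Matches) triple for each district:
#' C1 and C2 come from the deduplicated day counts, M is the number of
#' matched pairs whose day-1 record lies in that district (matches across
#' nearby districts are attributed to the day-1 side).
#'
#' @param match_set A match set from [match_rosters()].
#' @param day_counts Day counts from [day_counts()], covering both days.
#' @return Data.frame with columns `district`, `c1`, `c2`, `m`.
#' @export
tally_districts <- function(match_set, day_counts) {
  stopifnot(inherits(match_set, "match_set"), is.data.frame(day_counts))
  districts <- sort(unique(day_counts$district))
  c1 <- vapply(districts, function(d) {
    sum(day_counts$count[day_counts$district == d & day_counts$day == 1L])
  }, numeric(1))
  c2 <- vapply(districts, function(d) {
    sum(day_counts$count[day_counts$district == d & day_counts$day == 2L])
  }, numeric(1))
  pairs <- match_set$pairs
  if (nrow(pairs) > 0L) {
    unknown <- setdiff(unique(pairs$day1_district), districts)
    if (length(unknown) > 0L) {
      stop("tally consistency error: match pair in unknown district: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  m <- vapply(districts, function(d) {
    sum(pairs$day1_district == d)
  }, numeric(1))
  new_tally(districts, c1, c2, m)
}

#' Lincoln-Petersen population estimate
#'
#' The classical two-sample estimator C1 * C2 / M of the total population
#' size. Provided as a diagnostic comparator for the census-style total.
#'
#' @param c1,c2,m Count 1, Count 2 and matched-pair totals (vectorised).
#' @return Numeric estimate(s); `m` must be >= 1.
#' @export
lincoln_petersen <- function(c1, c2, m) {
  if (any(m < 1)) {
    stop("lincoln_petersen undefined for M = 0", call. = FALSE)
  }
  c1 * c2 / m
}

#' Chapman small-sample population estimate with 95% interval
#'
#' The bias-corrected two-sample estimator
#' (C1 + 1)(C2 + 1)/(M + 1) - 1, defined even when M = 0, with a 95%
#' normal-approximation interval from the standard variance
#' (C1+1)(C2+1)(C1-M)(C2-M) / ((M+1)^2 (M+2)), truncated below at the
#' number of distinct individuals observed (C1 + C2 - M).
#'
#' @param c1,c2,m Count 1, Count 2 and matched-pair totals (scalars).
#' @return List with `estimate`, `se`, and `ci95` (length-2 vector).
#' @export
chapman <- function(c1, c2, m) {
  stopifnot(length(c1) == 1L, length(c2) == 1L, length(m) == 1L,
            c1 >= 0, c2 >= 0, m >= 0, m <= min(c1, c2))
  est <- (c1 + 1) * (c2 + 1) / (m + 1) - 1
  v <- (c1 + 1) * (c2 + 1) * (c1 - m) * (c2 - m) / ((m + 1)^2 * (m + 2))
  se <- sqrt(v)
  lo <- max(est - 1.959963984540054 * se, c1 + c2 - m)
  hi <- est + 1.959963984540054 * se
  list(estimate = est, se = se, ci95 = c(lo, hi))
}

#' Census-style population estimate for one district
#'
#' The study estimator: the number not seen in either count is
#' U = C1 * C2 / M, and the reported total is
#' T = round(C1 + C2 + M + U) with halves away from zero. The total sums
#' the first count, the second count, the matched individuals and the
#' unseen — so matched individuals are counted in C1, in C2 *and* in M,
#' and T always exceeds the Lincoln-Petersen estimate by C1 + C2 + M.
#' The corrective multiplier k = T / C1 (2 decimals, from the rounded
#' total) expresses how far a single street count falls short.
#'
#' Districts with C1 + C2 below `min_combined` are excluded (the match
#' rate is too imprecise there); districts with M = 0 get an explicit
#' undefined status rather than a division by zero.
#'
#' @param c1,c2,m Count 1, Count 2 and matched-pair counts (scalars).
#' @param min_combined Minimum C1 + C2 for estimation (default 25).
#' @return List with `U`, `T`, `k`, `status` (one of `"estimated"`,
#'   `"excluded_small_counts"`, `"undefined_zero_matches"`).
#' @export
estimate_district <- function(c1, c2, m, min_combined = 25) {
  stopifnot(length(c1) == 1L, length(c2) == 1L, length(m) == 1L)
  if (c1 < 0 || c2 < 0 || m < 0) {
    stop("estimate validation error: negative counts", call. = FALSE)
  }
  if (m > min(c1, c2)) {
    stop("estimate validation error: M exceeds min(C1, C2)", call. = FALSE)
  }
  if (c1 + c2 < min_combined) {
    return(list(U = NA_real_, T = NA_real_, k = NA_real_,
                status = "excluded_small_counts"))
  }
  if (m == 0) {
    return(list(U = NA_real_, T = NA_real_, k = NA_real_,
                status = "undefined_zero_matches"))
  }
  U <- c1 * c2 / m
  T_raw <- c1 + c2 + m + U
  T_rounded <- round_half_away(T_raw)
  k <- round_half_away(T_rounded / c1, 2)
  list(U = U, T = T_rounded, k = k, status = "estimated")
}

#' Estimate all districts of a tally table
#'
#' Applies [estimate_district()] to each row of a tally table.
#'
#' @param tallies Data.frame with columns `district`, `c1`, `c2`, `m`.
#' @param min_combined Minimum C1 + C2 for estimation (default 25).
#' @return Data.frame with columns `district`, `c1`, `c2`, `m`, `U`,
#'   `T`, `k`, `status`.
#' @export
estimate_population <- function(tallies, min_combined = 25) {
  stopifnot(is.data.frame(tallies),
            all(c("district", "c1", "c2", "m") %in% names(tallies)))
  rows <- lapply(seq_len(nrow(tallies)), function(i) {
    est <- estimate_district(tallies$c1[i], tallies$c2[i], tallies$m[i],
                             min_combined = min_combined)
    data.frame(district = tallies$district[i],
               c1 = tallies$c1[i], c2 = tallies$c2[i], m = tallies$m[i],
               U = est$U, T = est$T, k = est$k, status = est$status,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate district estimates to an all-areas summary
#'
#' Sums the rounded per-district totals over districts with status
#' `"estimated"`, sums their C1 / C2 / M columns, and reports the range of
#' corrective multipliers. Excluded and undefined districts are listed
#' separately, never silently dropped into the totals.
#'
#' @param estimates Output of [estimate_population()].
#' @return List with `total`, `c1`, `c2`, `m`, `k_range` (min, max),
#'   `n_estimated`, `excluded` and `undefined` district labels.
#' @export
aggregate_estimates <- function(estimates) {
  stopifnot(is.data.frame(estimates),
            all(c("district", "c1", "c2", "m", "T", "k", "status")
                %in% names(estimates)))
  est <- estimates[estimates$status == "estimated", , drop = FALSE]
  list(
    total = sum(est$T),
    c1 = sum(est$c1),
    c2 = sum(est$c2),
    m = sum(est$m),
    k_range = if (nrow(est) > 0L) c(min(est$k), max(est$k)) else numeric(0),
    n_estimated = nrow(est),
    excluded = estimates$district[estimates$status == "excluded_small_counts"],
    undefined = estimates$district[estimates$status == "undefined_zero_matches"]
  )
}

#' Packaged published tally fixture
#'
#' The nine printed per-district (Count 1, Count 2, Matches) triples from
#' the two-day Cambodian street census of homeless 13-17 year olds, as
#' shipped with the package. These are the inputs to the estimator; the
#' published totals are what [estimate_population()] reproduces from them.
#'
#' @return Data.frame with columns `province`, `district`, `c1`, `c2`, `m`.
#' @export
table1_tallies <- function() {
  path <- system.file("extdata", "table1_tallies.csv",
                      package = "streetcensus", mustWork = TRUE)
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  out$c1 <- as.integer(out$c1)
  out$c2 <- as.integer(out$c2)
  out$m <- as.integer(out$m)
  out
}
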