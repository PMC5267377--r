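# End-to-end orchestration: dedup -> match -> tally -> estimate -> stats,
# with file outputs mirroring the census tables. Used by the numbered
# analysis scripts; every stage is also callable on its own.

#' Run the full census pipeline on two day rosters
#'
#' Executes the analysis chain: within-day deduplication of both rosters,
#' cross-day matching, per-district tallies, the census-style population
#' estimates with the small-count exclusion rule, the all-areas
#' aggregate, and (optionally) characteristic summaries of the combined
#' deduplicated respondents. Deterministic: no randomness is consumed.
#'
#' @param day1,day2 Raw (pre-dedup) single-day rosters.
#' @param geo A [geography()]; defaults to [default_geography()].
#' @param threshold,review_floor,recall_floor,distinctiveness Matching
#'   parameters, see [match_rosters()].
#' @param min_combined Estimation exclusion threshold, see
#'   [estimate_district()].
#' @param out_dir Optional directory; when given, writes `matches.csv`,
#'   `estimates.csv`, `characteristics.csv` and `summary.txt` there.
#' @param verbose Log stage-by-stage counts to standard error.
#' @return List with `dedup1`, `dedup2`, `counts`, `matches`, `tallies`,
#'   `estimates`, `summary`, `characteristics`.
#' @export
run_pipeline <- function(day1, day2, geo = default_geography(),
                         threshold = 0.80, review_floor = 0.60,
                         recall_floor = 0.50,
                         distinctiveness = default_distinctiveness(),
                         min_combined = 25, out_dir = NULL,
                         verbose = FALSE) {
  if (threshold <= 0 || threshold > 1) {
    stop("pipeline config error: threshold must lie in (0, 1]",
         call. = FALSE)
  }
  if (min_combined < 0) {
    stop("pipeline config error: min_combined must be >= 0", call. = FALSE)
  }
  say <- function(...) if (verbose) message("[", format(Sys.time(), "%H:%M:%S"),
                                            "] ", ...)
  say("dedup: day 1 (", nrow(day1), " records), day 2 (", nrow(day2), ")")
  dd1 <- dedup_within_day(day1)
  dd2 <- dedup_within_day(day2)
  say("dedup retained ", nrow(dd1$retained), " + ", nrow(dd2$retained),
      " records (dropped ", nrow(dd1$dropped) + nrow(dd2$dropped), ")")
  counts <- day_counts(dd1$retained, dd2$retained)
  ms <- match_rosters(dd1$retained, dd2$retained, geo,
                      threshold = threshold, review_floor = review_floor,
                      recall_floor = recall_floor,
                      distinctiveness = distinctiveness)
  say("matching: ", nrow(ms$pairs), " pairs from ", ms$n_candidates,
      " candidates")
  tallies <- tally_districts(ms, counts)
  estimates <- estimate_population(tallies, min_combined = min_combined)
  summary <- aggregate_estimates(estimates)
  say("estimation: total ", summary$total, " across ", summary$n_estimated,
      " district(s)")
  characteristics <- characteristics_summary(
    rbind(dd1$retained, dd2$retained), "sex")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(ms$pairs, file.path(out_dir, "matches.csv"),
                     row.names = FALSE, na = "")
    utils::write.csv(estimates, file.path(out_dir, "estimates.csv"),
                     row.names = FALSE, na = "")
    utils::write.csv(characteristics,
                     file.path(out_dir, "characteristics.csv"),
                     row.names = FALSE, na = "")
    writeLines(c(
      sprintf("all-areas total estimate: %s", summary$total),
      sprintf("count totals: C1 = %d, C2 = %d, M = %d",
              summary$c1, summary$c2, summary$m),
      if (length(summary$k_range) == 2L) {
        sprintf("corrective multiplier range: %.2f - %.2f",
                summary$k_range[1], summary$k_range[2])
      } else "corrective multiplier range: (none estimated)",
      sprintf("districts estimated: %d; excluded (small counts): %s; undefined (zero matches): %s",
              summary$n_estimated,
              if (length(summary$excluded)) paste(summary$excluded, collapse = ", ") else "none",
              if (length(summary$undefined)) paste(summary$undefined, collapse = ", ") else "none")
    ), file.path(out_dir, "summary.txt"))
  }
  list(dedup1 = dd1, dedup2 = dd2, counts = counts, matches = ms,
       tallies = tallies, estimates = estimates, summary = summary,
       characteristics = characteristics)
}
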