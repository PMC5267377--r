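#' Within-day deduplication by the same-day cartoon rule
#'
#' Each enumerated adolescent is shown the day's unique cartoon; anyone
#' who reports having already been shown it earlier the same day is an
#' already-counted duplicate and is not counted again. This drops every
#' record with `saw_today_cartoon = TRUE` and retains all others, in the
#' original order. It is the only within-day duplicate control: same-day
#' re-encounters that go unreported (a dishonest or forgetful answer)
#' remain in the counts.
#'
#' @param roster A single-day roster data.frame.
#' @return List with `retained` and `dropped` rosters
#'   (`retained` + `dropped` partition the input).
#' @export
dedup_within_day <- function(roster) {
  validate_roster(roster)
  if (nrow(roster) > 0L && length(unique(roster$day)) != 1L) {
    stop("dedup precondition error: records span more than one day",
         call. = FALSE)
  }
  flagged <- !is.na(roster$saw_today_cartoon) & roster$saw_today_cartoon
  retained <- roster[!flagged, , drop = FALSE]
  dropped <- roster[flagged, , drop = FALSE]
  rownames(retained) <- NULL
  rownames(dropped) <- NULL
  list(retained = retained, dropped = dropped)
}

#' Per-district day counts
#'
#' Counts retained records per (district, day): the "Count 1" / "Count 2"
#' columns of the census table.
#'
#' @param ... One or more deduplicated roster data.frames (e.g. the
#'   retained day-1 and day-2 rosters).
#' @return Data.frame with columns `district`, `day`, `count`; one row per
#'   (district, day) present in the input.
#' @export
day_counts <- function(...) {
  rosters <- list(...)
  combined <- do.call(rbind, rosters)
  if (is.null(combined) || nrow(combined) == 0L) {
    return(data.frame(district = character(0), day = integer(0),
                      count = integer(0), stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(list(count = combined$record_id),
                          by = list(district = combined$district,
                                    day = combined$day),
                          FUN = length)
  agg <- agg[order(agg$district, agg$day), , drop = FALSE]
  rownames(agg) <- NULL
  agg$count <- as.integer(agg$count)
  agg
}
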