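# Descriptive comparison of respondent characteristics across sex or age
# group: proportion tables with explicit missingness, Pearson chi-squared
# tests and two-sample t-tests.

#' Pearson chi-squared test on a contingency table
#'
#' Pearson's chi-squared without continuity correction;
#' df = (rows - 1)(cols - 1), p from the upper tail. Degenerate tables
#' (a zero row or column marginal) are rejected rather than silently
#' yielding NaN expectations.
#'
#' @param counts Numeric matrix of cell counts.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
chi_squared_test <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(is.numeric(counts), all(counts >= 0),
            nrow(counts) >= 2L, ncol(counts) >= 2L)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("degenerate table: zero row or column marginal", call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = unname(res$p.value))
}

#' Two-sample t-test
#'
#' Two-sided two-sample t-test, Welch (unequal variances) by default with
#' Welch-Satterthwaite degrees of freedom; set `var_equal = TRUE` for the
#' pooled-variance variant.
#'
#' @param values_a,values_b Numeric vectors (each with >= 2 non-missing
#'   values).
#' @param var_equal Assume equal variances (default FALSE = Welch).
#' @return List with `statistic`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
t_test <- function(values_a, values_b, var_equal = FALSE) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stop("insufficient data: each group needs >= 2 values", call. = FALSE)
  }
  res <- stats::t.test(values_a, values_b, var.equal = var_equal)
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = unname(res$p.value),
       mean_a = mean(values_a), mean_b = mean(values_b))
}

group_labels <- function(roster, grouping) {
  if (grouping == "sex") {
    list(values = roster$sex, groups = c("male", "female"))
  } else if (grouping == "age_group") {
    g <- ifelse(is.na(roster$age), NA_character_,
                ifelse(roster$age <= 14L, "13-14", "15-17"))
    list(values = g, groups = c("13-14", "15-17"))
  } else {
    stop("unknown grouping: ", grouping, call. = FALSE)
  }
}

#' Proportion table for one characteristic
#'
#' Cross-tabulates one characteristic field of a respondent roster by sex
#' or by age group (13-14 versus 15-17), in the style of a published
#' descriptive table: counts and column percentages for all respondents
#' and per group, missing values excluded from denominators and reported
#' as `n_missing`, and a Pearson chi-squared homogeneity test across the
#' groups (when the table is non-degenerate).
#'
#' @param roster A respondent roster data.frame.
#' @param variable One of [characteristic_columns()].
#' @param grouping `"sex"` or `"age_group"`.
#' @return Object of class `"proportion_table"`: list with `variable`,
#'   `grouping`, `counts` (categories x groups incl. "all"), `percent`
#'   (column percentages, 2 decimals), `n_missing`, `test`
#'   (chi-squared result or NULL if degenerate).
#' @export
proportion_table <- function(roster, variable, grouping = c("sex", "age_group")) {
  grouping <- match.arg(grouping)
  validate_roster(roster)
  if (!variable %in% characteristic_columns()) {
    stop("unknown characteristic variable: ", variable, call. = FALSE)
  }
  vals <- roster[[variable]]
  if (is.logical(vals)) vals <- ifelse(vals, "yes", "no")
  grp <- group_labels(roster, grouping)
  keep <- !is.na(vals) & !is.na(grp$values)
  n_missing <- sum(is.na(vals))

  cats <- sort(unique(vals[keep]))
  groups <- grp$groups
  counts <- matrix(0L, nrow = length(cats), ncol = length(groups) + 1L,
                   dimnames = list(cats, c("all", groups)))
  for (g in groups) {
    tab <- table(factor(vals[keep & grp$values == g], levels = cats))
    counts[, g] <- as.integer(tab)
  }
  counts[, "all"] <- as.integer(table(factor(vals[keep], levels = cats)))

  totals <- colSums(counts)
  percent <- counts
  percent[] <- 0
  nonzero <- totals > 0
  percent[, nonzero] <- round_half_away(
    sweep(counts[, nonzero, drop = FALSE], 2, totals[nonzero], "/") * 100, 2)

  test <- NULL
  grp_counts <- counts[, groups, drop = FALSE]
  if (nrow(grp_counts) >= 2L &&
      !any(rowSums(grp_counts) == 0) && !any(colSums(grp_counts) == 0)) {
    test <- chi_squared_test(grp_counts)
  }
  structure(
    list(variable = variable, grouping = grouping, counts = counts,
         percent = percent, n_missing = n_missing, test = test),
    class = "proportion_table"
  )
}

#' @export
print.proportion_table <- function(x, ...) {
  cat("Characteristic:", x$variable, "by", x$grouping,
      sprintf("(missing = %d)\n", x$n_missing))
  show <- matrix(
    sprintf("%d (%.2f%%)", x$counts, x$percent),
    nrow = nrow(x$counts), dimnames = dimnames(x$counts))
  print(show, quote = FALSE)
  if (!is.null(x$test)) {
    cat(sprintf("chi-squared = %.4f, df = %d, p = %.4f\n",
                x$test$statistic, x$test$df, x$test$p_value))
  }
  invisible(x)
}

#' Characteristic summary across all fields
#'
#' Runs [proportion_table()] for every characteristic field and flattens
#' the result into one long data.frame suitable for CSV export.
#'
#' @param roster A respondent roster.
#' @param grouping `"sex"` or `"age_group"`.
#' @return Data.frame with columns `variable`, `category`, `group`,
#'   `count`, `percent`, `n_missing`, `chisq_statistic`, `chisq_df`,
#'   `chisq_p`.
#' @export
characteristics_summary <- function(roster, grouping = c("sex", "age_group")) {
  grouping <- match.arg(grouping)
  blocks <- lapply(characteristic_columns(), function(v) {
    pt <- proportion_table(roster, v, grouping)
    if (nrow(pt$counts) == 0L) {
      return(data.frame(variable = v, category = NA_character_,
                        group = NA_character_, count = NA_integer_,
                        percent = NA_real_, n_missing = pt$n_missing,
                        chisq_statistic = NA_real_, chisq_df = NA_real_,
                        chisq_p = NA_real_, stringsAsFactors = FALSE))
    }
    grid <- expand.grid(category = rownames(pt$counts),
                        group = colnames(pt$counts),
                        stringsAsFactors = FALSE)
    data.frame(
      variable = v, category = grid$category, group = grid$group,
      count = pt$counts[cbind(grid$category, grid$group)],
      percent = pt$percent[cbind(grid$category, grid$group)],
      n_missing = pt$n_missing,
      chisq_statistic = if (is.null(pt$test)) NA_real_ else pt$test$statistic,
      chisq_df = if (is.null(pt$test)) NA_real_ else pt$test$df,
      chisq_p = if (is.null(pt$test)) NA_real_ else pt$test$p_value,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}
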