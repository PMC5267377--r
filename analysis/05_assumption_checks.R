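#!/usr/bin/env Rscript
# How the estimators behave when the dual-system assumptions hold and
# when they are violated. Under a closed population with independent
# lists and perfect matching, Lincoln-Petersen is near-unbiased and the
# Chapman 95% interval covers the truth at its nominal rate; the
# census-style total sits above the truth by construction (it re-counts
# the observed). Positive list dependence inflates the overlap and biases
# every estimator down. Uniform out-migration alone merely thins list 2
# (the estimators stay centred); it is population turnover — departures
# plus fresh arrivals who can appear in Count 2 but can never match —
# that breaks closure upward. 200 closed-form capture replicates per scenario,
# N = 500, p1 = p2 = 0.4, perfect matching throughout (the linkage stage
# is scored separately in 03).

library(streetcensus)

set.seed(405)
n_true <- 500L
n_rep <- 200L

scenario <- function(label, delta = 0, migration_out = 0, migration_in = 0) {
  lp <- cen <- chap <- numeric(n_rep)
  cover <- logical(n_rep)
  n_arrivals <- round(migration_in * n_true)
  for (r in seq_len(n_rep)) {
    cap1 <- runif(n_true) < 0.4
    stay <- runif(n_true) >= migration_out
    p2 <- plogis(qlogis(0.4) + delta * cap1)
    cap2 <- (runif(n_true) < p2) & stay
    c1 <- sum(cap1); m <- sum(cap1 & cap2)
    c2 <- sum(cap2) + rbinom(1, n_arrivals, 0.4)
    lp[r] <- lincoln_petersen(c1, c2, m)
    cen[r] <- estimate_district(c1, c2, m)$T
    ch <- chapman(c1, c2, m)
    chap[r] <- ch$estimate
    cover[r] <- ch$ci95[1] <= n_true && n_true <= ch$ci95[2]
  }
  data.frame(scenario = label, delta = delta, migration_out = migration_out,
             migration_in = migration_in,
             mean_lincoln_petersen = mean(lp), mean_chapman = mean(chap),
             mean_census_total = mean(cen),
             chapman_coverage = mean(cover))
}

out <- rbind(
  scenario("assumptions hold"),
  scenario("positive list dependence", delta = 1),
  scenario("negative list dependence", delta = -1),
  scenario("out-migration only 10%", migration_out = 0.10),
  scenario("turnover 10% out + 10% in", migration_out = 0.10,
           migration_in = 0.10)
)
dir.create("results", showWarnings = FALSE)
write.csv(out, "results/assumption_checks.csv", row.names = FALSE)

cat(sprintf("True population per replicate: %d (x%d replicates per scenario)\n\n",
            n_true, n_rep))
print(out, row.names = FALSE, digits = 4)
cat("\nReading: with assumptions met, Lincoln-Petersen ~ 500 and Chapman\n")
cat("coverage ~ 0.95, while the census-style total ~ 500 + C1 + C2 + M.\n")
cat("Positive dependence deflates all three; uniform out-migration is\n")
cat("neutral (it only thins list 2); turnover with fresh arrivals inflates.\n")
cat("\nWrote results/assumption_checks.csv\n")
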