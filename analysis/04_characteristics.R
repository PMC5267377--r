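#!/usr/bin/env Rscript
# Descriptive characteristics of the simulated respondents, presented the
# way a street-census report tabulates them: per-variable counts and
# column percentages by sex and by age group (13-14 vs 15-17), missing
# answers reported per variable, chi-squared homogeneity tests, and a
# Welch t-test for mean age by sex.

library(streetcensus)

day1 <- read_roster("results/sim/day1.csv")
respondents <- dedup_within_day(day1)$retained

by_sex <- characteristics_summary(respondents, "sex")
by_age <- characteristics_summary(respondents, "age_group")
write.csv(by_sex, "results/characteristics_by_sex.csv", row.names = FALSE)
write.csv(by_age, "results/characteristics_by_age.csv", row.names = FALSE)

cat(sprintf("Respondents (deduplicated day-1 roster): %d\n\n",
            nrow(respondents)))
print(proportion_table(respondents, "caregiver", "sex"))
cat("\n")
print(proportion_table(respondents, "school_attendance", "age_group"))

age_m <- respondents$age[respondents$sex == "male"]
age_f <- respondents$age[respondents$sex == "female"]
tt <- t_test(age_m, age_f)
cat(sprintf("\nMean age: males %.2f vs females %.2f; Welch t = %.3f, df = %.1f, p = %.4f\n",
            tt$mean_a, tt$mean_b, tt$statistic, tt$df, tt$p_value))
cat("\nWrote results/characteristics_by_sex.csv and results/characteristics_by_age.csv\n")
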