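---
title: "Dual-system street-census estimation: model, matching and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-system street-census estimation: model, matching and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(streetcensus)
```

## The estimation problem

Street-dwelling adolescents are a hidden population: any single
enumeration pass misses an unknown fraction of them. Dual-system
estimation (two-sample capture-recapture) turns that unknown into an
estimable quantity by running two independent counts on separate days
and measuring their overlap. If a fraction M/C2 of the day-2 count was
already seen on day 1, then — under the assumptions below — day 1 saw
roughly that same fraction of everyone, so the day-1 count C1 scales up
to C1·C2/M.

The assumptions, each of which this package can deliberately violate in
simulation:

* **Closure** — nobody enters or leaves the area between the counts
  (`migration_out`, `migration_in` break this);
* **List independence** — being counted on day 1 does not change the
  chance of being counted on day 2 (`delta`, a log-odds shift on the
  day-2 capture probability of day-1 captures, breaks this);
* **Perfect matchability** — individuals seen twice can be recognised as
  the same person (transliteration noise on romanized names,
  `name_noise_prob`, breaks this).

## The census-style estimator

For a district with counts C1, C2 and matches M, the number seen by
neither count is estimated as U = C1·C2/M, and the reported total is

    T = round(C1 + C2 + M + U),   k = T / C1 (two decimals),

both rounded half-away-from-zero. This total intentionally **re-counts
matched individuals**: it sums the first count, the second count, the
matched individuals *and* the unseen, so its unrounded value always
equals the Lincoln–Petersen estimate C1·C2/M plus C1 + C2 + M (an
identity asserted in the test suite). Standard two-list theory would
instead report C1 + C2 − M + U; the census-style total is what the
source analysis computed — every one of its printed district totals,
their 2,697 sum and the 3.53–27.08 multiplier range is reproduced
exactly by this arithmetic — so the package implements it as the primary
estimator and documents, rather than resolves, the discrepancy. The
classical comparators are available as `lincoln_petersen()` and
`chapman()` (the latter small-sample-corrected, defined at M = 0, with a
normal-approximation 95% interval truncated below at the number of
distinct individuals observed).

Numerical choices that matter for exact reproduction:

* **Rounding** is half-away-from-zero (`round_half_away()`), not R's
  banker's rounding: 149.5 must become 150 while 384.25 stays 384.
* **The multiplier divides the rounded total** by C1: 67/19 = 3.53,
  whereas 67.2/19 would print 3.54.
* **The exclusion rule** drops districts with C1 + C2 < 25 from
  estimation (the match rate is too imprecise there). The raw sum of the
  two counts is used, not the count of distinct children
  (C1 + C2 − M); the phrase "across both counts" reads most naturally as
  the former, and the threshold is a configurable argument
  (`min_combined`) for anyone preferring the other reading.
* **M = 0** in a non-excluded district yields an explicit
  `undefined_zero_matches` status, never a division by zero.

## Record linkage

Candidate day-1 × day-2 pairs are blocked to the **same city and the
same or adjacent district** — enumerated children move around, but not
between cities on consecutive days — then scored by the weighted
agreement of eight identifying fields. Name fields use a normalized
Levenshtein similarity (1 − edit distance / longer length); sex and
province compare exactly; age is scored 1 − min(|Δage|, 2)/2. The
linkage weight is the distinctiveness-weighted mean over the fields
available on both sides:

    w = Σᵢ fᵢ·sᵢ / Σᵢ fᵢ  ∈ [0, 1].

Default distinctiveness f: given and family name 3, parents' names 2,
age 2, nickname/sex/province 1. Names differentiate individuals most;
sex (two levels) and province (a handful of levels around each city)
differentiate least. The original analysis used a record-linkage
package whose internal weight scale is not recoverable; this package
defines its own normalized scale, so the 0.80 threshold is comparable
only within this implementation. Pairs with fewer than two available
fields are incomparable and skipped (counted in `n_incomparable`).

Matching proceeds in three additive one-to-one tiers:

1. **auto** — w ≥ 0.80, assigned greedily by descending weight;
2. **phonetic** — w in [0.60, 0.80) with equal phonetic keys on both
   given and family name, equal sex, age within one year. This is a
   deterministic stand-in for the clerical review step of the original
   study, whose manually recovered matches were predominantly
   phonetic-spelling cases; a hand review cannot be reproduced, a key
   comparison can.
3. **recall** — still-unmatched day-2 respondents who correctly recalled
   the day-1 cartoon, paired with their best remaining candidate if
   w ≥ 0.50.

The phonetic key uppercases, maps the aspirated digraphs PH/TH/KH/CH to
P/T/K/C, drops an H after a consonant, collapses repeated letters and
drops non-leading vowels — so Chan/Chann, Sok/Sokh, Thida/Tida collapse,
while genuinely different names keep distinct keys. The review and
recall floors (0.60, 0.50) have no published counterpart; they are
explicit, tunable parameters chosen so that each lower tier admits only
pairs that already agree on most of their weight.

Assignment is greedy on descending weight with a deterministic,
label-symmetric tie-break (the unordered record-id pair), so a run is
reproducible and swapping the two rosters yields the same pair set.
Globally optimal assignment was considered and not made the default:
at these weights the greedy and optimal solutions differ only on ties,
and greedy is auditable row by row. Tiers are additive only — a later
tier can never remove an earlier tier's pair — because whether the
original clerical review could overturn an automatic match is unknown.

## The synthetic census generator

The generator emulates the study conditions; its defaults are not
free dials but the conditions themselves:

* **True district populations** default to the nine estimated totals
  (636 … 650, 2,697 in all) — the best available description of the
  population the counts sampled.
* **Capture probabilities** default to the overall observed coverage of
  each count: p1 = 282/2697 ≈ 0.105, p2 = 221/2697 ≈ 0.082.
* **Closure and independence hold by default** (`migration_* = 0`,
  `delta = 0`): key informants reported that short-term movement was
  low, and no quantitative violation is published. Scenario analyses
  must state the values they switch on.
* **Sex and age marginals** come from the published respondent profile
  (64.32% male; ages 35.11/22.87/21.81/10.11/10.11% for 13–17). The
  printed age percentages sum to 100.01%, so the configured vector is
  renormalised proportionally at validation (tolerance 0.01).
  Characteristic fields (caregiver, schooling, literacy, work, chores,
  interference, injury, illness, safety, trust) are drawn from the
  published marginal shares with the published per-variable missingness.
* **Observation nuisances** have no published rates and were fixed once
  at values a field team would recognise: 5% same-day duplicate
  encounters, 90% honest same-day cartoon answers, 70% correct
  next-day cartoon recall, 15% transliteration noise per name field.

Names come from a packaged bank of ~130 romanized Khmer-style given and
family names, each with at least two hand-listed spelling variants
(Chan/Chann, Sok/Sokh, Phally/Phaly/Faly). Transliteration noise
substitutes a listed variant — never a random character edit — because
that is the failure mode of transcribing spoken Khmer names into Roman
script. Two design consequences:

* **Identity uniqueness.** The generator resamples name draws so that no
  two persons in the same city share both family and given name. True
  homonyms are indistinguishable to any name-based linkage, so without
  this the true match set would be unrecoverable in principle and the
  noise-free exact-recovery test would measure homonym frequency, not
  linkage correctness. Near the bank's combinatorial capacity (~4,100
  name pairs per city) the resampling is best-effort and warns; linkage
  experiments use city populations of at most ~1,000, well inside it.
* **Some variants cross phonetic keys** (Faly vs Phally): those pairs
  are exactly the ones the weight tier, not the phonetic tier, must
  recover — mirroring the division of labour in the original study.

All draws come from one seeded stream in a fixed documented order
(population first, then capture flags, migration, recall, per-day
duplicate and honesty flags, name noise field by field), so identical
config + seed gives byte-identical rosters. What the generator does
**not** emulate: real Khmer name frequencies (the bank is uniform),
within-day spatial drift, enumerator-level behaviour, age- or
sex-dependent capture probabilities, and children misreporting age or
sex. Passing recovery tests therefore demonstrate that the pipeline is
correct under the modelled noise structure — not that the original
field matching achieved any particular accuracy on real data.

## Characteristic comparisons

`proportion_table()` reproduces the descriptive-table style of the
study: counts and column percentages per group (all/male/female, or
13–14 vs 15–17), missing answers excluded from denominators and
reported per variable, Pearson chi-squared without continuity
correction across groups, and a two-sided Welch t-test for continuous
comparisons (the pooled-variance variant is an option; the published
analysis does not state which was used, and its p-values are not
reproducible without the unpublished interview records — the printed
cell values are used only to calibrate the generator, never as test
oracles). No multiple-testing adjustment is applied, mirroring the
per-variable presentation of the source tables.

## Problem sizes and runtime envelope

The test suite and acceptance script size their simulations to what the
checks need statistically, not more: marginal calibration at
5,000–20,000 persons (binomial standard errors around 0.5%), noise-free
linkage recovery at 650 persons per run across three seeds, noisy
linkage at 300 persons × 20 replicates (enough for every replicate to
hold precision and recall above 0.9 with margin), Chapman coverage at
500 replicates of N = 500 (Monte-Carlo standard error on coverage
≈ 1 point). A full suite run takes well under a minute.

## Known limitations

* The census-style total overstates a closed population by construction
  (it re-counts the observed); it is reproduced faithfully, with the
  classical estimators alongside for anyone who wants the standard
  answer.
* Single-digit match counts make the multipliers fragile: one match
  more or fewer in Siem Reap (24, 25, M = 1) moves the district total
  by hundreds. The package surfaces this through the Chapman interval
  rather than attempting an interval for the nonstandard total.
* The matching thresholds live on this package's own weight scale;
  0.80 here is not the 0.80 of any other record-linkage system.
* Undetected same-day duplicates (dishonest cartoon answers) remain in
  the counts by design — the cartoon question is the only within-day
  control the method specifies.
* The characteristic enumerations mirror the published table's row
  labels; which options were pre-coded versus free-text in the field
  instrument is not recorded.
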