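Package: streetcensus
Title: Two-Sample Capture-Recapture Estimation for Street-Census Rosters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dual-system (two-sample capture-recapture) estimation of
    hidden urban populations from two-day street-census rosters. Provides a
    synthetic roster generator with transliteration name noise and ground
    truth, within-day deduplication via a same-day cartoon rule, cross-day
    probabilistic record linkage with threshold, phonetic-review and
    cartoon-recall tiers, a census-style population estimator with a
    small-count exclusion rule and corrective multipliers, Lincoln-Petersen
    and Chapman comparison estimators, and Table-style descriptive
    comparisons of respondent characteristics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
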