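Package: crimelink
Title: Cohort-to-Police-Records Linkage with Synthetic Evaluation Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A two-stage pipeline linking a birth-cohort roster to a regional
    police register: deterministic matching on personal identifiers with
    postcode-based match-strength tiers, Fellegi-Sunter probabilistic scoring
    with blocking and string-similarity comparators, twin and low-confidence
    manual-review rules, duplicate resolution, disposal-outcome filtering of
    crime event records (single-offender and group crimes), crime-harm
    severity scoring with cumulative multipliers, statistical disclosure
    control (pseudonymisation, age-in-months conversion, top-coding,
    small-cell suppression), and per-birthday residence flags for denominator
    definition. Includes a synthetic-data generator with configurable
    identifier-corruption processes and a ground-truth link table so every
    stage can be evaluated without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    stringr,
    rlang,
    lubridate,
    readr,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
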