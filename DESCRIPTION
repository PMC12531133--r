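Package: pvsignal
Title: Pharmacovigilance Signal Detection for Checkpoint-Inhibitor Aseptic Meningitis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A spontaneous-report analysis pipeline for drug safety signal
    detection, built around immune-checkpoint-inhibitor-associated aseptic
    meningitis in FAERS-style individual case safety report (ICSR) databases.
    Provides readers and writers for '$'-delimited quarterly-ASCII-style and
    CSV report tables, preferred-term query matching against a noninfectious
    meningitis term set, rule-based deduplication and temporal-plausibility
    filtering, regimen classification (monotherapies, ipilimumab+nivolumab
    combination, drug classes), four frequentist and Bayesian-family
    disproportionality statistics (ROR, PRR with Pearson chi-squared,
    information component, empirical Bayes geometric mean) with
    per-algorithm signal thresholds and a two-method concordance rule,
    stratified descriptive summaries with time-to-onset analysis, and a
    synthetic ICSR database generator with planted association strengths for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    rlang,
    stats,
    utils,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
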