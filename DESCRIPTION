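Package: pvfaers
Title: Pharmacovigilance Signal Detection and Time-to-Onset Analysis for
    FAERS-Style Spontaneous Report Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for disproportionality analysis of spontaneous adverse
    event reports in the FDA Adverse Event Reporting System (FAERS)
    quarterly ASCII format. Reads and deduplicates quarterly report tables,
    maps free-text drug names to normalized drugs, selects drug-event cases
    by MedDRA preferred term, and computes four signal-detection statistics
    (reporting odds ratio, proportional reporting ratio with chi-square,
    Bayesian confidence propagation neural network information component,
    and the empirical Bayes geometric mean of the gamma-Poisson shrinker)
    with interval estimates and standard positivity criteria, overall and
    within sex and age subgroups. Includes descriptive case tables with
    chi-square homogeneity tests, time-to-onset summaries with Kaplan-Meier
    curves and log-rank comparisons, a configurable synthetic FAERS
    generator with planted association strengths for validation, and a
    single-configuration pipeline driver with a reproducibility manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    survival,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
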