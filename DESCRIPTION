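Package: faersdpa
Title: Disproportionality and Time-to-Onset Analysis for FAERS Spontaneous Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pharmacovigilance signal-detection toolkit for FDA
    Adverse Event Reporting System (FAERS) quarterly ASCII extracts. Reads and
    normalizes the DEMO/DRUG/REAC/THER tables, deduplicates case versions,
    builds per-drug 2x2 contingency tables for a target MedDRA preferred term,
    and computes four disproportionality statistics with signal criteria: the
    reporting odds ratio (ROR), the proportional reporting ratio (PRR) with
    Pearson chi-squared, the multi-item gamma Poisson shrinker (MGPS;
    EBGM/EB05), and the Bayesian confidence propagation neural network
    information component (IC/IC025). Includes Weibull time-to-onset analysis
    with the shape-parameter (failure type) test, a synthetic FAERS-format
    data generator with a ground-truth ledger for validation, and a
    replication mode that applies the signal criteria directly to published
    statistic tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    withr,
    optparse
Config/testthat/edition: 3
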