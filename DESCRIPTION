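Package: spotdiff
Title: Differential Two-Dimensional Gel Electrophoresis Analysis and
    Peptide Mass Fingerprinting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for differential protein-expression analysis of
    two-dimensional gel electrophoresis (2DE) experiments at the spot-table
    level: reading, normalising and cross-gel matching of spot tables,
    spot-volume-quotient (SVQ) differential calling with a multi-gel coverage
    rule and an exact Mann-Whitney U-test, multi-spot protein aggregation and
    functional-category summaries. Includes a simplified peptide-mass-
    fingerprint search engine (tryptic in-silico digestion, fixed and variable
    modifications, ppm matching, probability-based MOWSE-style scoring with a
    Mascot-style significance threshold) and a synthetic-data generator that
    emulates multi-stage replicate 2DE experiments and MALDI peak lists so the
    whole pipeline is testable without raw gels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tibble,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
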