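Package: coexnull
Title: Monte Carlo Null Models for Neuronal Transmitter Coexpression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates and scores models of transmitter coexpression in a
    fixed neuron population. Provides an independent-expression Monte Carlo
    null model (random assignment of transmitter-positive labels to cells),
    a rule-constrained variant in which chosen directed coexpression
    probabilities are clamped to observed values, standard-deviation-index
    (SDI) statistics for ranking models against observed coexpression,
    deterministic reconstruction of per-cell fixture data from published
    summary percentages, a synthetic multi-replicate data generator with
    planted dependencies for end-to-end validation, and relative-expression
    (delta-Ct, 2^-delta-Ct) analysis of qPCR Cq tables with nondetect
    handling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
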