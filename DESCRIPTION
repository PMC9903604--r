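Package: triadexpress
Title: Expression-Pattern Classification and Heterosis Statistics for
    Hybrid-Parent Triads
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Tools for analysing gene expression in a hybrid and its two
    parental lines (an M/H/P triad), as used in studies of seed-coat
    heterosis in maize. Provides FPKM normalisation, replicate averaging
    and correlation, expressed-gene calling and multi-set overlap
    accounting, pairwise Welch differential expression with
    Benjamini-Hochberg correction and fold-change call rules, a 13-class
    additive / expression-level-dominance / transgressive classification
    of every gene from its three pairwise contrasts with high-/mid-/
    low-parent summarisation, mid-parent-value phenotype statistics
    (relative growth rate, hybrid-vs-MPV tests, seed-coat cell density,
    qPCR 2^-ddCt), and a negative-binomial triad simulator with known
    per-gene class truth so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
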