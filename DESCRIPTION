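Package: herbnet
Title: Network Pharmacology Validation for Multi-Herb Prescriptions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds filtered herb-ingredient-gene-disease networks from
    SymMap-style relational tables, statistically validates the disease sets
    predicted for each multi-herb prescription against curated gold-standard
    clinical indications using a size-matched permutation null model with
    empirical p-values, and runs dose-weighted pre-ranked gene-set enrichment
    analysis (running-sum enrichment score, gene-label permutation null, NES,
    Benjamini-Hochberg FDR, leading-edge extraction). Includes a synthetic
    knowledge-base generator with planted ground truth so every stage of the
    pipeline is testable without external databases, plus exporters for
    GraphML, SIF and tab-separated result tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
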