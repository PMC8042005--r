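Package: chapatlas
Title: Tissue Landscape Analysis of the Human Chaperone System
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for the expression landscape of molecular
    chaperones across human tissues. Provides a curated-registry loader,
    per-tissue expression breadth profiling, one-vs-rest tissue differential
    expression (TMM scaling factors, mean-variance precision weights, and
    empirical-Bayes moderated t-statistics implemented from first principles),
    a core-versus-variable gene classification rule, per-tissue Spearman
    co-expression networks with pair-class statistics, CRISPR essentiality
    summaries, development and aging stage comparisons, an exact
    overlap-enrichment statistics kernel, and a seeded multi-tissue
    negative-binomial simulator with planted ground truth for end-to-end
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    edgeR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
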