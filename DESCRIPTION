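Package: orthodev
Title: Cross-Species Comparative Developmental Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing developmental gene expression programs between
    two related species. Implements negative-binomial differential expression
    between consecutive embryonic stages, K-means coexpression clustering with
    stage-archetype labelling, orthogroup parsing and ortholog expression
    conservation statistics (shared/exclusive differential expression,
    stage synchrony, cluster overlap), in-paralog expression divergence
    classification, bait-gene correlation networks with percentile-derived
    cutoffs, hypergeometric term over-representation, and a fully labelled
    two-species synthetic count simulator for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
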