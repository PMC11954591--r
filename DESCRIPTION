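Package: cnpgls
Title: Phylogenetic Regression of Gene Copy Number on Life-History and
    Cancer Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative analysis of gene copy-number evolution
    across a species phylogeny. Implements weighted phylogenetic
    generalized least squares (PGLS) with profiled Pagel's lambda,
    per-orthogroup association screens against longevity, body size and
    necropsy-derived cancer phenotypes, an aggregate gene-set copy-number
    test, variance-matched gene-set and Brownian-motion phenotype
    randomization nulls, a Poisson phylogenetic GLM for reversed
    count-on-trait models, preranked gene set enrichment analysis with the
    classic statistic, hypergeometric overrepresentation analysis, and a
    synthetic-data generator producing trees, tree-correlated copy-number
    matrices and phenotypes with known planted effects.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    withr,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
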