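Package: fruitbody
Title: Ancestral Gene-Expression Evolution of Fungal Fruiting-Body Development
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative transcriptomics of perithecium development
    in Neurospora and Fusarium: normalisation of stage-resolved RNA-seq counts
    to relative expression profiles, a signed stage-to-stage fold-change
    statistic and its inverse, maximum-likelihood continuous ancestral
    character estimation under Brownian motion on a fixed species chronogram,
    directional ranking of genes by evolved expression divergence between
    ancestral nodes to prioritise knockout candidates, knockout-phenotype /
    expression-stage concordance scoring, exact enrichment statistics, and
    score-based Bayesian network structure learning with model-averaged
    consensus graphs per phylogenetic node. Includes a fully specified
    synthetic-data generator so the whole pipeline is testable without any
    download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
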