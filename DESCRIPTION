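Package: traitlink
Title: Trait-Ontology Annotation of Association-Mapping Results and
    Co-Expression Modules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds gene-to-trait-ontology annotation tables from
    association-mapping summary statistics by assigning significant
    markers to genes within linkage-disequilibrium flanking windows, and
    analyses the resulting tables with ontology-aware tooling:
    hypergeometric gene-set enrichment against any annotation source,
    information-content semantic similarity between phenotype profiles,
    false-positive-rate simulation with random gene sets, and Markov
    cluster (MCL) partitioning of co-expression networks.  Includes a
    synthetic-data generator that emits toy ontologies (OBO), gene models
    (GFF3), association tables and expression matrices with known ground
    truth, and a command-line interface composing the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    utils
Suggests:
    igraph,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
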