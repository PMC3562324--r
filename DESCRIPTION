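Package: cazclust
Title: CAZyme Gene Cluster Enrichment and Fungal Genome Architecture
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Analyse the genomic architecture of carbohydrate-active enzyme
    (CAZyme) genes in fungal genome assemblies. Enumerates candidate gene
    clusters bounded by CAZyme genes and scores them with an exact
    hypergeometric upper-tail statistic, merges significant clusters into
    enzyme-dense regions, locates terminal telomeric tandem-repeat arrays
    and classifies putative chromosomes, labels enriched regions as
    sub-telomeric by distance to chromosome ends, detects runs of adjacent
    plant cell wall-degrading enzyme genes with a global-alignment paralogy
    filter, computes genome annotation summary statistics, and normalises
    cross-species category counts to percent of the per-category maximum.
    A synthetic genome-annotation simulator with recorded ground truth
    supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    GenomeInfoDb,
    S4Vectors,
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
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
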