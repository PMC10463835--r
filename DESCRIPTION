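Package: spikegwas
Title: Genotype-Phenotype Mapping of Wheat Spike Morphology and Assimilate
    Partitioning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, simulation-backed pipeline for dissecting cereal
    spike morphology into assimilate-partitioning ratio traits and mapping
    them: variant filtering from VCF, broad-sense heritability and best
    linear unbiased estimates from multi-year trials, mixed-linear-model
    genome-wide association with simple-matching kinship and principal
    component covariates, permutation and Bonferroni significance
    thresholds, LD-based delineation of association peaks, candidate-gene
    windowing with expression filtering, and gene-level haplotype analysis
    including geographic and temporal frequencies and Tajima's D. A
    synthetic-data generator with block-structured linkage disequilibrium
    and pleiotropic QTLs provides a ground-truth test surface for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    withr,
    lme4,
    igraph,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
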