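Package: poolscan
Title: QTL Mapping from Pooled Exome Sequencing of Phenotypically Contrasting Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for extreme-phenotype association mapping from pooled
    sequencing of contrasting variety sets (bulked segregant analysis of a
    quantitative trait in an inbred crop panel). Selects phenotypically
    extreme high/low sets under a genetic-distance constraint, checks the
    selection for population-structure confounding, reads pooled variant
    calls with per-pool allele depths, applies a quality/fixed-allele/depth
    filtering cascade, scans for associations by the allele frequency
    difference (AFD) between pools, clusters associated markers into QTL
    under a centromere-aware independence rule, and validates pooled
    frequency estimates and marker-trait associations against individual
    genotypes. Includes a synthetic-data generator (inbred panels with
    planted additive QTL and binomially sampled pooled read counts) so the
    whole pipeline is testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
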