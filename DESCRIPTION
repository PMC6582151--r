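Package: bulkqtl
Title: Bulk-Segregant QTL Mapping and Forward Simulation of Nematode
    Segregant Pools
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for extreme quantitative trait locus (X-QTL) mapping in
    outcrossing Caenorhabditis elegans segregant pools. Provides a forward
    simulator of multigenerational bulk-segregant populations (single-crossover
    meiosis on a genetic map, X/0 sex determination, fitness-weighted mating,
    a paternal-toxin/zygotic-antidote selfish element, and truncation selection
    parameterised by variance explained), and the pooled-sequencing scan
    statistics: a modified G statistic on pooled allele counts, tri-cube kernel
    smoothing in genetic distance, a robust log-normal null for p-values,
    simulation-based confidence intervals for peaks, selection-coefficient
    estimation from allele-frequency trajectories, and expression-QTL LOD
    mapping with permutation-based FDR control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
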