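Package: hicphaser
Title: Cancer Genome Haplotype Phasing from Hi-C Proximity Ligation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Phases cancer genomes into chromosome-level haplotypes using
    Hi-C paired-end linkage. Filters somatic SNPs against a known germline
    site list, detects loss-of-heterozygosity (LOH) regions with a windowed
    exact binomial test against a normal-genome heterozygosity profile,
    phases non-LOH stretches into haplotype blocks, corrects switch errors
    from allelic read-coverage imbalance, assembles fragmented blocks by
    partitioning a coverage matching graph with a randomized contraction
    heuristic for the minimum multiple s-t cut problem, and completes
    chromosomes by connecting LOH sequences to haplotypes via exhaustive
    enumeration. Includes a ground-truthed simulator and evaluation metrics
    (absolute error rate, block completeness, LOH precision/sensitivity).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    GenomicAlignments,
    ggplot2,
    igraph,
    IRanges,
    purrr,
    Rcpp,
    rlang,
    Rsamtools,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
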