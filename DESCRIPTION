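Package: recmapr
Title: Recombination Landscapes from Genetic Linkage Maps and Genome Sequence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates local meiotic recombination rates in fixed genomic
    windows from one or more genetic linkage maps anchored to a genome
    assembly (the Marey-map approach), screens the maps for conflicts
    between genetic and physical marker order, and relates the per-window
    rates -- and their cross-map average and variance -- to DNA sequence and
    gene-annotation features: GC content, CpG abundance, exhaustive di-,
    tri- and tetra-nucleotide composition, selected longer motifs,
    microsatellite and low-complexity coverage, and gene/intron statistics.
    Feature-rate relationships are assessed with FDR-corrected bivariate
    correlations, backward stepwise regression on standardized predictors,
    and principal-component analysis of k-mer composition with PC-vs-rate
    regression. A seeded simulator generates toy genomes, annotations and
    marker sets with a known GC-coupled recombination landscape so the full
    pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
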