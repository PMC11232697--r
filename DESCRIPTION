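Package: neosexkit
Title: Detection, Phasing and Degeneration Analysis of Neo-Sex Chromosomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing young neo-sex chromosomes from population
    resequencing data: detection of a non-recombining neo-W from
    sex-contrasted heterozygosity and genotype PCA, Bayesian change-point
    segmentation of windowed neo-W/neo-Z divergence into plateaus, phasing of
    neo-W haplotypes from sex-diagnostic alleles, a perfect-phylogeny test of
    whether neo-W variation fits a single genealogy with folded variant-type
    spectra and neutral-coalescent expectations, and quantification of neo-W
    degeneration (loss-of-function load, relative coverage, allele-specific
    expression). A built-in block-wise coalescent simulator of a Z-autosome
    fusion with recombination-rescue plateaus generates fully specified
    synthetic datasets with ground truth, so the whole analysis runs at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    generics,
    withr,
    stats,
    utils,
    ape,
    vcfR,
    Biostrings,
    IRanges,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
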