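Package: cottonpop
Title: Population Genomics of Divergence, Domestication and Introgression
    in Allotetraploid Cottons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a resequencing-style population
    genomic analysis for the two cultivated allotetraploid cottons
    (Gossypium hirsutum and G. barbadense): variant filtering and SNP
    category classification, windowed nucleotide diversity and Hudson
    F_ST, a pi-ratio selective-sweep scan with permutation false-positive
    estimation, homoeologous sweep pairing and QTL overlap, block-level
    neighbor-joining phylogenies for introgression event calling with
    direction and subgenome bias tests, the f3 three-population admixture
    statistic with block-jackknife standard errors, genome-wide
    simple-matching distances, NJ trees and variance-normalised PCA, and
    expression-based candidate-gene rules. A Balding-Nichols synthetic
    genotype simulator for a two-species tetraploid panel (A and D
    subgenomes, race/cultivar bottleneck, planted sweeps and
    introgression blocks) makes every stage testable without external
    data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
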