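Package: wgdkit
Title: Whole-Genome Duplication Dating and Assembly Validation from
    Synteny, Ks and Read-Coverage Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for reconstructing the polyploid history of plant
    genomes and validating draft assemblies. Implements Nei-Gojobori
    (1986) pairwise Ka/Ks estimation with Jukes-Cantor correction,
    collinear anchor chaining into synteny blocks, block-median Ks
    histograms and modal-peak detection, algebraic solving of branch
    lengths on a species/duplication event tree from modal Ks
    observations with calibration to absolute ages, per-base synteny
    coverage-depth profiling, k-mer histogram genome-size estimation,
    classification of collapsed versus repeated-non-collapsed assembly
    regions from three-mode read-mapping coverage, assembly and genetic
    map summary statistics, in-silico PCR marker placement, and a fully
    synthetic data generator with known ground truth for end-to-end
    testing of every stage.
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
    S4Vectors,
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
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
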