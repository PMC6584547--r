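Package: hlacall
Title: HLA Class-I Genotyping from Short Reads by a Variational Bayes
    Read Mixture Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers diploid HLA class-I genotypes from short-read
    sequencing data by assigning multi-mapped reads across a panel of
    allele reference sequences with a Dirichlet-multinomial mixture
    model fitted by variational Bayes (an EM mode is provided as a
    maximum-likelihood cross-check).  Includes the surrounding toolkit:
    parsing of HLA allele nomenclature, reference-panel handling with
    exon/intron feature annotations, augmentation of a base panel with
    full-length population-specific alleles, exon-2/3 identity
    (G-group-style ambiguity) analysis, a depth-based diploid genotype
    caller with an explicit fail state, typing-concordance evaluation
    (accuracy, discordance and ambiguity reports), and a seeded
    simulator generating synthetic panels and diploid read sets with
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    graphics,
    utils,
    Rcpp,
    Biostrings,
    Rsamtools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
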