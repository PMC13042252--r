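Package: sweepscan
Title: Simulation-Trained Detection and Classification of Hard and Soft
    Selective Sweeps from Unphased Genotypes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A windowed genome-scan pipeline for detecting recent positive
    selection in unphased diploid genotype data and distinguishing hard from
    soft selective sweeps. Labeled training data are generated by coalescent
    simulation under user-supplied piecewise-constant demographic histories
    and wide priors on mutation, recombination and selection parameters; each
    simulated or empirical window is summarized by twelve population-genetic
    statistics computed in eleven adjacent subwindows and row-normalized into
    a spatial feature matrix; a small convolutional softmax network assigns
    each window a posterior over five classes (neutral, hard, hard-linked,
    soft, soft-linked). Post-classification inference includes
    simulation-null false discovery rates and q-values for candidate sweeps,
    a conservative confusion-matrix correction of the soft-sweep fraction,
    and permutation enrichment tests (gene-set label shuffling and circular
    chromosome rotation) for annotation overlap.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
SystemRequirements: python (>= 3.8) with msprime (>= 1.0) on the PATH, used
    by the coalescent simulation backend.
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
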