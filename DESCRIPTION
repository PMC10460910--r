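Package: traitarch
Title: Genetic Architecture of Binary Traits in Structured Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for dissecting the genetic architecture of a
    binary (case/control) trait in a structured animal population. Provides
    synthetic cohort simulation with known ground truth (multi-generation
    pedigrees, LD-structured haplotypes, liability-threshold phenotypes,
    selective sweeps), genotype quality control and PLINK/VCF input-output,
    genomic and pedigree relationship matrices, a Bayesian probit animal model
    for liability-scale heritability, mixed-model genome-wide association with
    permutation significance thresholds, regional (window) heritability
    scanning with two variance components, haplotype-based selection-signature
    statistics (nucleotide diversity, iHS, nSL, H12) combined by the
    decorrelated composite of multiple signals (DCMS), Bayesian whole-genome
    probit regression (Bayesian ridge, BayesB, BayesC, Bayesian LASSO) for
    polygenic risk prediction, and cross-validated evaluation on the liability
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    MASS,
    glmnet,
    randomForest,
    xgboost,
    jsonlite,
    yaml,
    vcfR,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
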