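Package: msatabc
Title: Approximate Bayesian Computation for Microsatellite Demographic
    Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Coalescent simulation of competing population
    divergence/bottleneck scenarios under generalized stepwise
    microsatellite mutation with single-nucleotide indels, DIYABC-style
    summary statistics, and Approximate Bayesian Computation: rejection
    sampling, scenario choice by multinomial logistic regression,
    logit-transformed local-linear parameter adjustment, posterior
    predictive model checking and PCA pre-evaluation. Includes the
    descriptive microsatellite diversity report (observed/effective
    allele numbers, heterozygosity, inbreeding coefficient) and mtDNA
    haplotype statistics (indel-aware haplotype collapsing, haplotype
    and nucleotide diversity), Genepop and FASTA input/output, and
    synthetic-data generators for end-to-end validation without any
    external download.
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
    ggplot2,
    generics,
    nnet,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    withr
Config/testthat/edition: 3
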