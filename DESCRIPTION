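Package: breedgain
Title: Realized Genetic Gain Estimation and Stochastic Breeding Program Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for long-term self-pollinating crop breeding programs. A
    three-stage weighted mixed-model pipeline estimates realized genetic gain
    from historical multi-environment trial records (per-trial adjusted means
    and plot-basis heritability, weighted joint and pedigree animal-model
    analyses, and a gain regression on year or generation of origin), together
    with pedigree utilities (additive relationship matrix, generation
    counting) and trial quality control (Bonferroni outlier removal,
    heritability filtering, connectivity audits). A stochastic forward
    simulator with Rcpp meiosis kernels compares phenotypic, genomic-selection
    (RRBLUP), and high-throughput-phenotyping breeding frameworks and
    optimizes the number of parents, crosses, and progeny per cross via
    replicated factorial experiments, variance-component decomposition, and
    Scott-Knott clustering of means.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    Matrix,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
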