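Package: cwmphylo
Title: Community-Weighted Genome Size, Nutrient Effects and Phylogenetic
    Mixed Models for Grassland Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse how genome size (1C-value) and ploidy shape
    plant community biomass under factorial nitrogen and phosphorus
    fertilization. Computes biomass-weighted community mean genome size
    per subplot, partitions biomass into genomic groups (ploidy crossed
    with a genome-size threshold) and Grime C-S-R strategy components,
    and tests nutrient effects with sequential-sums-of-squares factorial
    ANOVA, random-intercept linear mixed models with likelihood-ratio
    model reduction, phylogenetic signal statistics (Blomberg's K with a
    permutation test, Pagel's lambda by maximum likelihood), phylogenetic
    generalized least squares, and a Bayesian phylogenetic mixed model
    fitted by a conjugate Gibbs sampler. A synthetic-community generator
    (birth-death tree, Brownian trait evolution with tunable signal,
    factorial nutrient design, log-scale biomass) makes every stage
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    nlme,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    coda,
    jsonlite,
    phytools,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
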