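Package: crabflow
Title: Landscape Genetics of Crop-to-Wild Gene Flow in Apples
Version: 0.1.0
Authors@R:
    person("crabflow", "maintainers", email = "crabflow@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for landscape-genetics analyses of
    crop-to-wild introgression and within-species spatial genetic
    structure from microsatellite genotypes: Gibbs-sampler inference of
    admixture proportions with Evanno delta-K model choice and replicate
    alignment, threshold-based hybrid classification and introgression
    rates, diversity statistics (heterozygosities, Weir-Cockerham
    F-statistics, rarefied allelic and private allelic richness),
    Loiselle kinship with isolation-by-distance regression and the Sp
    statistic, and quasi-Poisson GLMs linking introgression and
    flower-visitor diversity to landscape covariates. Includes a
    synthetic-data generator (F-model clusters, hybrid pedigrees,
    spatially limited dispersal, covariate-linked introgression) so the
    full pipeline is testable without field data, plus GENEPOP I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
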