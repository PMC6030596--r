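Package: seabirdFMR
Title: Phylogenetic Meta-Analysis and Prediction of Seabird Field Metabolic Rate
Version: 0.1.0
Authors@R:
    person("FMR", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Fits Bayesian phylogenetic mixed models to literature-compiled
    field metabolic rate (FMR) records from breeding seabirds, using a Gibbs
    sampler with parameter-expanded priors on random-effect variances
    (phylogeny, species and colony) and a Brownian-motion correlation matrix
    derived from a phylogeny. Provides DIC-based model selection, highest
    posterior density intervals, pMCMC statistics, phylogenetic heritability,
    jackknife resampling diagnostics, a prediction engine that returns daily
    FMR estimates with HPD bounds for arbitrary (species, mass, latitude,
    breeding phase) queries, and a synthetic-data generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
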