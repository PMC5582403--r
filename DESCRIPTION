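Package: snapburst
Title: Bayesian Inference of Transcriptional Bursting Kinetics from smFISH
    Population Snapshots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers the kinetic parameters of stochastic promoter-switching
    (telegraph) models of gene expression from time-resolved population
    snapshots of single-molecule RNA FISH data, i.e. per-cell counts of mRNA
    molecules and active transcription sites before and after a stimulus.
    Solves the chemical master equation on a truncated state space (sparse
    generator, uniformization-based matrix-exponential action, stationary
    null-space solve), scores parameter sets with a product-of-multinomials
    snapshot likelihood, samples the Bayesian posterior with a Metropolis
    random walk, and ranks competing parameter-stimulus hypotheses with BIC,
    AICc and DIC. Includes a synthetic-snapshot generator and an independent
    Gillespie stochastic-simulation oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
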