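Package: mcrs
Title: Metabolically Coupled Replicator Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic cellular-automaton simulator of surface-bound prebiotic
    replicators coupled through a common metabolism. Each replicator carries two
    enzyme activities and a basic replication rate under a three-way trade-off;
    populations evolve on a toroidal lattice by constant-rate death,
    metabolism-weighted replication lotteries, uniform mutant sampling from the
    feasible trait volume, conformation switching and site-swap diffusion. The
    package classifies phenotypes into specialist, generalist, parasite and
    intermediate classes, records per-generation summaries and enzyme-activity
    histograms, and orchestrates parameter sweeps with crossover estimation for
    the specialist/generalist phase transition. A compiled kernel makes
    desk-scale replicates of the published experiments tractable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
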