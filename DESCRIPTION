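Package: phyloroot
Title: Rooting Phylogenetic Trees with Non-Reversible and Non-Stationary
    Substitution Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian inference of rooted phylogenies from nucleotide
    alignments without an outgroup, using two substitution models whose
    likelihood depends on the position of the root: a stationary,
    branch-homogeneous but non-reversible model (NR) built as a perturbed
    HKY85 process, and a non-stationary, branch-heterogeneous model (HB) in
    which the GTR composition vector drifts across branches. Includes
    Metropolis-Hastings MCMC over rooted topologies, branch lengths and model
    parameters, a sequence simulator for both models, and posterior summaries:
    root-split posteriors, majority-rule consensus trees, branch GC ranking,
    and standardized marginal likelihood curves.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
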