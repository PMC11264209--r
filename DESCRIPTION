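Package: tispath
Title: Transition Interface Sampling, Free-Energy Profiling and
    Dynamics-Guided Enzyme Redesign on Surrogate Rare-Event Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A toolkit for rare-event kinetics and dynamics-guided design:
    Langevin dynamics on desk-scale surrogate systems with a bond-exchange
    order parameter, transition interface sampling (TIS) with shooting-move
    Monte Carlo, rate-constant assembly from flux factors and interface
    conditional probabilities, umbrella sampling with WHAM unbiasing in
    screening and detailed modes, geometric feature extraction with
    reactive-like structural criteria, logistic-regression and neural-network
    classifiers that predict turnover success from prereaction conformations,
    a multistate sequence-design objective with stability constraints and
    exhaustive or branch-and-bound search, and the screening statistics
    (one-sided Mann-Whitney U, Benjamini-Hochberg FDR) used to compare
    designed variants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    glmnet,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
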