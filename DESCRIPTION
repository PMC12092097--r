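Package: pgsnet
Title: Polygenic Score Predictability on Simulated Gene Regulation Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation framework for studying how well additive polygenic
    scores predict phenotypes that are generated by nonlinear gene regulation
    networks. Generates signed weighted Erdos-Renyi regulatory networks,
    iterates Wagner-model sigmoidal dynamics to fixed-point equilibria,
    synthesises variational populations of individual networks, fits LASSO
    polygenic scores with cross-validated shrinkage, and dissects
    predictability via local stability analysis (Jacobian eigenvalues),
    variance-based global sensitivity analysis (Sobol first-order and total
    indices under Saltelli sampling), structural complexity metrics
    (two-component positive feedbacks, density, clustering), core/peripheral/
    remote classification of regulatory connections, and polygenic-score
    transferability across variation regimes and single-edge network mutants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
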