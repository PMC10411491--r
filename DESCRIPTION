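Package: mpcoevo
Title: Coevolution of mRNA Levels, Translation Rates, and Protein Levels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative-genetic simulation of the joint evolution of a
    gene's mRNA level, per-transcript translation rate, and protein level
    when selection acts on protein abundance. Implements an origin-fixation
    (sequential-fixation) engine with Gaussian stabilizing or directional
    selection, log-linear steady states for interacting gene regulatory
    networks, evolution along ultrametric phylogenies (Yule trees, Pagel
    lambda transforms), measurement-error injection, and downstream
    phylogenetic comparative analyses (Brownian-motion and
    Ornstein-Uhlenbeck maximum-likelihood fits, AICc weights, evolutionary
    correlations via independent contrasts, divergence-versus-time tables).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
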