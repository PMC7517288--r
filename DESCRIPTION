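Package: hyperpgg
Title: Public Goods Game Dynamics on Rank-3 Simple Hypergraphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for the evolution of cooperation
    under higher-order (group) interactions. Builds rank-3 simple hypergraphs by
    promoting a fraction of the 3-cliques of a clustered base network (Holme-Kim,
    Dorogovtsev-Mendes or Erdos-Renyi) to triangular hyperedges, runs synchronous
    public-goods-game dynamics with Fermi-rule imitation on the 2-section,
    measures structural reciprocity r(p) = alpha_surv/alpha_cr, and provides the
    accompanying closed-form layer: mean-field critical synergy with finite-size
    correction, cooperator-hub invasion thresholds, isolated-defector
    survival/invasion probabilities, degree/clustering competition conditions,
    degree- and clustering-preserving null-model rewirings, and topological-trap
    censuses.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
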