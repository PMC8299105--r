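Package: fungalnet
Title: Niche Breadth Classification and Ensemble Co-Occurrence Networks for
    Microbial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for identifying generalist and habitat-specialist taxa in
    OTU count tables via Levins' niche-breadth index, inferring ensemble
    co-occurrence networks from five association measures with permutation
    nulls, bootstrap stability and Brown's dependent p-value combination,
    characterising node roles (centralities, modules, Zi-Pi hubs), and
    estimating standardized total effects of spatial, climatic and edaphic
    drivers over a declared acyclic path diagram. Includes a synthetic
    community generator with planted ground truth so every stage can be
    validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    vegan,
    biomformat,
    multcomp,
    stats,
    graphics,
    utils,
    tools,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
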