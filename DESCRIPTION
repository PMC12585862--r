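Package: commassembly
Title: Stochastic Assembly of Microbial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and exact analytics for the stochastic assembly of
    microbial communities from a fixed species pool. Replicate communities
    assemble through dispersal from the pool and logistic division up to a
    carrying capacity; the package provides an exact Gillespie simulator
    (with optional death rates and unsaturated dispersal), a fast
    embedded-jump-chain sampler of final compositions, master-equation
    solutions for abundance fluctuation distributions, closed-form
    monodominance and co-occurrence probabilities, neutral moment
    recursions and analytic bimodality coefficients, plus empirical
    diagnostics (bimodality coefficient, mean relative abundance, richness,
    co-occurrence fraction, Bray-Curtis dissimilarity) on replicate
    abundance tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    vegan,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
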