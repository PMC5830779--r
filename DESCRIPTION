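Package: bnscreen
Title: Therapeutic Target Screening on Logic-Based Network Models
Version: 1.0.0
Authors@R:
    person("bnscreen", "developers", email = "bnscreen@example.org",
           role = c("aut", "cre"))
Description: Attractor-based identification of therapeutic targets in
    logic-based models of biological networks. Given a physiological and a
    pathological variant of a Boolean or multivalued logical model, the
    package enumerates candidate interventions ("bullets": combinations of
    node forcings), recomputes the attractor landscape of the perturbed
    pathological variant, and retains interventions that enlarge the union
    of the physiological basins of attraction without creating de novo
    attractors. Attractors are deterministic cycles under synchronous
    updating, or terminal strongly connected components of the asynchronous
    state-transition graph found by long random walks with forward-set
    validation. Multivalued models use Zadeh (min/max/complement) logic on
    an evenly spaced h-level domain.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    Matrix,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
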