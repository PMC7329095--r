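Package: cimapr
Title: Stabilised Conditional-Independence Maps and Bayesian Network
    Structure Learning for Discrete Data
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Constraint-based structure learning for discrete data built
    around conditional-independence maps (CI-maps): a PC-style adjacency
    search driven by mutual-information G-tests with weakest-first edge
    ordering, three false-discovery-rate schedules (basic, interleaved,
    mini) and an optional false-negative-reduction policy based on
    chi-squared power analysis.  CI-maps are oriented into partially
    directed graphs via collider detection and Meek-rule closure, extended
    to directed acyclic graphs under mutual-information node orders
    (strongest-first, weakest-first or random) with acyclicity repair, and
    scored by the BIC.  A bootstrap procedure with hierarchical filtering
    selects the most representative CI-map around a target variable, as
    used for feature selection in magnetic resonance spectroscopy of brain
    tumours.  Includes BIF network input/output, ancestral forward
    sampling, quantile discretisation with a degrees-of-freedom category
    budget, a synthetic metabolite-table generator, and structure-error
    benchmarking drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    igraph,
    xml2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
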