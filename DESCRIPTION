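Package: spatialmm
Title: Mental-Model Simulation and Individual-Level Evaluation for Spatial
    Relational Reasoning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational cognitive models of spatial relational reasoning:
    a coordinate-based mental-model reasoner with four inference policies, the
    preferred-mental-model array builder PRISM with first-fit and first-free-fit
    insertion strategies, and a queue-based verbal reasoning model with a
    cardinal-direction extension; together with a transitive-closure logic
    oracle, five reference baselines, synthetic generators for four classic
    benchmark designs (figural, continuity, cardinal-direction preference, and
    small/large-scale arrangement verification), and a coverage-style
    individual-level predictive evaluation with co-optimality analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
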