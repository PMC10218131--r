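Package: mobgame
Title: Evolutionary Mobilization-Participation Games on Emergency Resource Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator for the asymmetric "mobilization-participation" game
    between government resource subjects (GRSs) and social resource subjects
    (SRSs) in public-health emergency resource support. Provides the two-role
    payoff model with reward and penalty interventions, a mean-field
    replicator-dynamics analyzer (expected gains, fixed points, Jacobian
    stability classification, trajectory integration), a typed-network data
    model with file I/O and a synthetic generator, a complex-network game
    engine with Boltzmann learning-object selection and Fermi strategy
    updating, and scenario runners for baseline, initial-condition, reward,
    and penalty experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse
Config/testthat/edition: 3
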