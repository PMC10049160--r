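Package: carbonscape
Title: Scenario-Based Land-Use Change Simulation and Ecosystem Carbon
    Storage Accounting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A coupled pipeline for patch-based cellular-automaton
    simulation of categorical land-use change under policy scenarios and
    ecosystem carbon-storage accounting from per-class carbon-density
    pools. Includes a land-expansion analysis stage that estimates
    per-class development probabilities from historical map pairs and
    spatial drivers with a random-forest ensemble, a demand-constrained
    patch-seeding allocation automaton, declarative scenario rules
    (natural evolution, ecological protection, economic development,
    planned development), GM(1,1) gray forecasting of carbon densities,
    map-agreement validation metrics (overall accuracy, Cohen's kappa,
    figure of merit), a land-use-intensity/carbon-storage coordination
    index on block grids, and standard deviational ellipse summaries.
    A synthetic-landscape generator with known ground truth makes every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ranger,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
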