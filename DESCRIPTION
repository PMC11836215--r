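Package: trygiveup
Title: Simulation and Analysis of Try-or-Give-Up Incentive Interventions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how incentive schemes reshape exploration in a
    finite-horizon "Try or Give-Up" search task. Provides the task environment
    (two 12-key matrices with exploration costs and four treatment schemes),
    an exact belief-state backward-induction solver for the optimal-strategy
    benchmark with an independent brute-force oracle, a threshold-strategy
    family evaluator, a library of round-playing agents including a
    propensity-learning agent, a synthetic-cohort generator emulating a
    three-block pre/treatment/post design, and the analysis pipeline for
    choice-classification rates, incentive-stripped payoffs, difference
    scores with confidence intervals, and simple condition-level tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
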