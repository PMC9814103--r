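Package: flowbo
Title: Batch Bayesian Optimization of Mixed Continuous and Categorical
    Flow Reaction Conditions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Mixed-variable batch Bayesian optimization for screening
    continuous-flow reaction conditions. Categorical reactor variables
    (micromixer type) are handled by one-hot encoding with
    nearest-vertex rounding, continuous variables are min-max scaled to
    the unit cube, and a Gaussian-process surrogate with a Matern-5/2
    ARD kernel drives a parallel lower-confidence-bound acquisition
    that proposes batches of q conditions per round via sequential
    hallucination (kriging believer). Ships transcriptions of two
    published 15-run optimization campaigns for the organocatalytic
    flow synthesis of biaryls, a seeded synthetic flow-yield benchmark
    with mixer-dependent optima, a replay/benchmark harness comparing
    acquisition strategies against random search, and a command-line
    interface for the propose/record/replay workflow.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    lhs,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
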