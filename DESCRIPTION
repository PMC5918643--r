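Package: fuzzyhybrid
Title: Hybrid Fuzzy Agent-Based and System-Dynamics Simulation of Health Interventions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the implementation of community health interventions with a
    hybrid model that couples a population of fuzzy agents to an institutional
    stock-and-flow model. Agent perceptions are linguistic variables (Low, Medium,
    High) with triangular membership functions whose defining constants are sampled
    per agent from normal distributions; agents interact through random or
    scale-free contact networks under pessimistic, optimistic, or realistic
    inference rules; agents are clustered by Low-membership intervals and the
    resulting discrepancy signal feeds back into a two-stock system-dynamics model
    whose investment outflow is driven by a nine-rule Mamdani fuzzy controller with
    centre-of-gravity defuzzification. Includes closed-form membership trajectories
    for linear and exponential base-variable paths, a scenario generator, seeded
    reproducible runs, CSV trajectory output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
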