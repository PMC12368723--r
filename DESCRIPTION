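Package: ibuopt
Title: Kinetic Simulation and Surrogate-Based Multiobjective Optimization
    of Ibuprofen Synthesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrated pipeline for optimizing the Pd-catalyzed
    carbonylation route to ibuprofen. A mass-action kinetics engine
    (mechanism-file driven, compiled right-hand side, stiff-capable
    integration via deSolve) simulates batch trajectories and extracts
    reaction time and conversion rate; a techno-economic model prices each
    run. Gradient-boosted surrogates, tuned by a snow ablation
    metaheuristic, emulate the simulator; TreeSHAP attributions rank input
    importance; constrained NSGA-II extracts a Pareto front and four named
    operating strategies; Monte Carlo perturbation quantifies prediction
    uncertainty and strategy robustness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    xgboost,
    jsonlite,
    yaml,
    lhs,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
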