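Package: hhabc
Title: Identifiability Analysis of the Hodgkin-Huxley Model with ABC-SMC
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates the Hodgkin-Huxley membrane and conductance equations
    under voltage clamp and four advanced stimulation protocols (anode break,
    threshold excitation, positive phase depolarization, oscillation
    induction), fits both the simplified six-rate and the full
    fourteen-parameter voltage-dependency forms of the model with an
    adaptive-tolerance sequential Monte Carlo approximate Bayesian
    computation (ABC-SMC) sampler, and characterizes posterior
    identifiability (practical versus structural) through weighted posterior
    summaries, rate-curve ensembles, pairwise correlations and ensemble
    protocol responses. A seeded synthetic voltage-clamp data generator
    stands in for historical recordings so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
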