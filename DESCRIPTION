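Package: mtagent
Title: Multi-Timescale Reinforcement-Learning Agent for Perceptual Decision Making
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates a two-alternative forced-choice task on a noisy scalar
    signal (a random-dots-like paradigm) and trains an actor-critic
    reinforcement-learning agent that reads banks of leaky integrators of the
    signal and of a constant "clock" input over multiple timescales. Provides
    single-timescale and clock-less comparison models (including the
    Ornstein-Uhlenbeck integrator with optimised decision threshold), analytic
    references (fixed-time observer accuracy, experimental psychometric curve,
    drift-diffusion coefficient of variation), and the operational measures
    used to characterise the learned strategy: signal neutrality
    (decision-aligned collapse of the decision variable across coherences),
    the scalar property of response times (Weber's law), and collapsing
    decision boundaries read out from the clock pathway.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    MASS
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
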