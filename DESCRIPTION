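Package: structlearn
Title: Structure Learning in Sensorimotor Association Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of serial stimulus-response learning on a
    3x3 grid, where each task is a bijective mapping of nine stimuli to nine
    responses drawn from structured families (identity, circular shifts, axis
    mirrors) or sampled at random. Provides four learning agents - a linear
    network trained by the delta rule, a Rescorla-Wagner reinforcement
    learner with softmax action selection, a flat Bayesian learner over all
    362,880 candidate mappings, and a hierarchical Bayesian learner that
    additionally infers the structure class - together with exact posterior
    inference via matrix permanents (Ryser's algorithm), Thompson-sampling
    action selection, a two-group serial-learning protocol, facilitation-ratio
    and nonparametric-test analyses, a forgetting-error taxonomy with
    structure-consistency scoring, trial-by-trial learning curves, and a
    synthetic-subject generator with lapse and forgetting processes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
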