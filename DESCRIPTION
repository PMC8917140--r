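Package: stopsignal
Title: Simulation and Hierarchical Bayesian Modelling of Stop-Signal Task Behaviour
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the stop-signal paradigm: simulation of adaptive-staircase
    stop-signal sessions (classical and tilt-discrimination variants), standard
    inhibition metrics (quantile-method SSRT, inhibition accuracy, go-failure
    rates, participant exclusion rules), an analytic ex-Gaussian horse-race
    likelihood with trigger- and go-failure mixtures, the Wiener first-passage
    time density for a four-parameter diffusion decision model of the Go task,
    hierarchical Bayesian estimation of both models by differential-evolution
    MCMC with convergence diagnostics, and a group-inference layer with paired
    tests, Holm correction, repeated-measures ANOVA and JZS Bayes factors.
    Includes a synthetic-study generator that emulates a two-task, three-condition
    within-subject design with known ground truth for recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    coda,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
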