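Package: gutsred
Title: Reduced GUTS Survival Models with Bayesian Uncertainty Propagation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toxicokinetic-toxicodynamic modelling of survival data with the
    reduced General Unified Threshold models of Survival (GUTS-RED-SD and
    GUTS-RED-IT). Scaled damage and survival are computed piecewise
    analytically under constant and time-variable exposure profiles;
    parameters are calibrated by adaptive Markov chain Monte Carlo and the
    joint posterior is propagated to the regulatory toxicity endpoints
    LC(x,t), exposure multiplication factors MF(x,t) (also known as LPx) and
    depuration times. Includes goodness-of-fit measures (NRMSE, posterior
    predictive checks, WAIC, PSIS-LOO) and a synthetic-data simulator for
    standard constant and pulsed experimental designs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils, tools, jsonlite, coda
Suggests: testthat (>= 3.0.0), deSolve, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
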