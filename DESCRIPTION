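Package: dynconf
Title: Attractor Network Dynamics of Perceptual Decisions and Confidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates sequences of two-alternative perceptual decisions with
    a reduced two-pool attractor neural network, including a corollary-discharge
    relaxation between trials, and analyses the resulting behaviour the way it
    is analysed in human psychophysics. Confidence is read out from the
    difference in pool firing rates at the moment of decision and mapped onto a
    discrete rating scale by histogram matching. The package calibrates the
    network per participant from mean response times and accuracies, estimates
    non-decision-time distributions as ex-Gaussians by moment deconvolution,
    fits the standard linear mixed model of sequential effects on response
    times, and contrasts the attractor account with an extended independent
    race model that relaxes between trials.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    lme4,
    lmerTest,
    jsonlite,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
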