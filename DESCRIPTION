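Package: adcontrol
Title: Uncertainty-Aware Control of Anaerobic Co-Digestion
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for controlling biogas production from anaerobic
    co-digestion of heterogeneous waste streams (food waste, agricultural
    waste, municipal solid waste) under feedstock uncertainty. Estimates
    biochemical composition (carbohydrate, lipid, protein, lignin) from
    elemental (ultimate) analysis by simplex-constrained least squares,
    fits weighted Gaussian kernel density models of composition per waste
    type, simulates a semi-batch ADM1 (Anaerobic Digestion Model No. 1)
    digester, and trains tabular control policies: finite-horizon backward
    dynamic programming for short-term target tracking, a discrete PID
    baseline, and policy mirror descent for long-term robust production
    with feed-storage inventory. Controller performance is scored by mean
    absolute error, coefficient of variation, and dynamic time warping
    loss.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
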