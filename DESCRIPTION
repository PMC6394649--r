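Package: cwresbias
Title: Structural Model Diagnostics for Nonlinear Mixed-Effects Models via
    Conditional Weighted Residual Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies and corrects structural misspecification in nonlinear
    mixed-effects (NLME) models through parametric modeling of conditional
    weighted residuals (CWRES). Provides a minimal first-order conditional
    estimation (FOCE) engine (simulation, empirical Bayes estimation,
    conditional moments, CWRES, population fitting), exact maximum-likelihood
    fitting of base and bin-mean extended mixed models to CWRES with a
    chi-square test on the objective-function improvement, density-based and
    randomized binning of the independent variable, and back-correction of
    conditional-prediction bias through the FOCE covariance. Bundled example
    models include one- and two-compartment intravenous-bolus pharmacokinetic
    models on an intravenous glucose tolerance test sampling design and a
    minimal glucose kinetics ODE demo.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    nlme,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
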