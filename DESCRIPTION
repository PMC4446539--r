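Package: gengrad
Title: Hierarchical Models and Repeated-Measures ANOVA for Generalization Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing stimulus-generalization gradients measured
    repeatedly over an ordered stimulus dimension. Provides a two-level
    Gaussian simulator for gradient data (random intercepts and slopes with a
    subject-level moderator and cross-level interaction), a balanced
    split-plot repeated-measures ANOVA with Mauchly's sphericity test and
    Greenhouse-Geisser, Huynh-Feldt and lower-bound corrections, a maximum
    likelihood / REML fitter for two-level linear mixed models with Wald
    tests, deviance comparisons and empirical-Bayes predictions, and a
    Monte-Carlo harness that compares the type-I error and power of the
    dichotomized-moderator ANOVA interaction test against the mixed-model
    cross-level Wald test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    lme4,
    car,
    jsonlite,
    withr
Config/testthat/edition: 3
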