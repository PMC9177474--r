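Package: phichoice
Title: Common-Currency Modelling of Choices Between Cognitive and Physical Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing demand-selection experiments in which people
    choose between a cognitive task (mental arithmetic of varying difficulty
    and imposed duration) and a physical task (carrying an empty or loaded
    bucket). Provides a trial-level synthetic data generator with a known
    generative model, aggregation of binary choices into per-participant and
    group choice probabilities, fully within-subjects repeated-measures ANOVA
    with partial eta-squared, paired t tests with Cohen's d and
    within-participant confidence intervals, and the common-currency effort
    model: a four-parameter logistic fitted over a grid of shift parameters
    (k for cognitive difficulty, h for physical difficulty) that maps task
    duration, cognitive difficulty, and bucket weight onto a single latent
    axis Phi, maximising the coefficient of determination.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
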