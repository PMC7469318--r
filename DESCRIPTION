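Package: qoldrop
Title: Longitudinal Quality-of-Life Models Under Informative Dropout
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits and compares four models for longitudinal health-related
    quality-of-life (HRQoL) scores subject to monotone, potentially
    informative dropout: the random-coefficients linear mixed model (LMM),
    the Diggle-Kenward selection model with a logistic dropout hazard, the
    pattern-mixture model with delta-method marginalization, and a
    shared-parameter joint model linking the score trajectory to a
    piecewise-exponential dropout hazard through its current true value.
    Includes a synthetic-trial generator emulating an oncology HRQoL study
    (two arms, eight scheduled visits over 36 months) with MCAR, MAR and
    MNAR dropout mechanisms and full ground truth for parameter-recovery
    experiments, plus reporting helpers that tabulate estimates, Wald
    confidence intervals and predicted score trajectories across models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    MASS,
    pracma,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    nlme,
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
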