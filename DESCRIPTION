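Package: fcrsel
Title: Component Selection for Nonparametric Functional Concurrent Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits the nonparametric concurrent regression model y(t) = f(t, x(t, .)) + e(t)
    for a functional response and functional covariate surfaces, using a smoothing-spline
    ANOVA decomposition of f over a tensor product of reproducing kernel Hilbert spaces
    (a cubic-spline Sobolev space in t and Gaussian-kernel spaces on the L2 covariate
    arguments). Main effects and interactions among the functional covariates are detected
    by an L1-type component-selection estimator: a budget-constrained nonnegative rescaling
    of the component kernels is estimated by block backfitting over representer
    coefficients, null-space coefficients, and component scales. Includes ridge-type
    estimation over all components, selection-then-refit estimation, empirical functional
    principal component score representations, a synthetic-data generator with
    Gaussian-process covariate surfaces, and a simulation harness reporting prediction
    error and selection accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
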