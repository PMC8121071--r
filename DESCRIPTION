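Package: nicheD2
Title: Mahalanobis Distance Niche Models with Robust Location and Scatter
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Presence-only ecological niche models built on the Mahalanobis
    distance, with three multivariate location and scatter estimators: the
    sample mean and variance-covariance, the minimum covariance determinant
    (MCD, FAST-MCD style C-step concentration), and the minimum volume
    ellipsoid (MVE, elemental-subset resampling). Squared distances are
    converted to niche probabilities through the chi-squared distribution.
    Includes a virtual-ecology toolkit: an elliptical Gaussian fundamental
    niche for a virtual species, logistic detection filtering, a synthetic
    climate sampling space, error and bias contamination of occurrence
    samples, and replicated experiments that score each estimator by the
    correlation between the known niche value and the modelled probability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
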