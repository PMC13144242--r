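Package: catlgm
Title: Scaling and Estimation of Latent Growth Models with Categorical
    Indicators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how ordinal and binary indicators scale the
    latent response variables of linear latent growth models. Provides the
    observed-scale-reference calculus (z-scale thresholds, unit lengths,
    common-scale means and standard deviations), a population growth model
    and synthetic panel generator for longitudinal categorical data, a
    two-stage threshold/polychoric estimator with diagonally weighted least
    squares under the delta parameterization (first-occasion scale factor
    fixed at one), and a Monte Carlo driver that summarises relative bias,
    root mean square error and estimation difficulties across simulation
    conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    MASS,
    mvtnorm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
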