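Package: flowgrade
Title: End-Product Assessment of Vascular Anastomoses from Hemodynamic Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Objective, end-product-based assessment of surgical vascular
    anastomoses from computational-fluid-dynamics-derived hemodynamic
    features. Computes wall shear stress indicators (TAWSS, OSI, RRT,
    transverse WSS, WSSG), vorticity, strain rate, energy loss and port
    flow quantities from time-resolved flow fields on triangulated vessel
    geometries; builds expert consensus scores with intraclass-correlation
    reliability statistics; fits a pool of regression models (ridge,
    partial least squares, kernel support vector regression, random
    forest, extremely randomized trees, gradient boosting) under nested
    cross-validation with a mu+lambda evolution-strategy hyperparameter
    search; and explains predictions with Shapley feature attributions.
    Includes a synthetic-data module generating analytic pulsatile flow
    fields with closed-form indicator values and full synthetic cohorts
    (correlated features, latent quality, noisy raters) for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
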