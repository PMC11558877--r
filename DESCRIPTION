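Package: smallgee
Title: Small-Sample Generalized Estimating Equations for Binary Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Marginal logistic regression for clustered and longitudinal
    binary outcomes when the number of clusters is small. Fits the
    conventional generalized estimating equations (GEE), a second-order
    bias-corrected variant (BCGEE), and a Firth-type penalized variant
    (PGEE) that remains finite under separation, each combinable with
    twelve sandwich-type covariance estimators (the unadjusted robust
    estimator and eleven small-sample adjustments: MK, KC, MD, FG, PA,
    GS, MB, WL, WB, FW, FZ). Includes a correlated-binary data generator
    based on a latent-normal threshold construction for simulation
    studies, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 3.5.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
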