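Package: funqr
Title: Quantile Regression for Longitudinal Functional Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scalar-on-function quantile regression for longitudinal and
    clustered data. Coefficient surfaces are represented by tensor-product
    penalized splines (cyclic in the within-day direction) and estimated by
    minimizing a smoothed (extended log-F) check loss with ridge-penalized
    subject-specific intercepts. Noisy functional covariates are pre-smoothed
    by functional principal component analysis with a percentage-of-variance
    truncation rule. Inference for quantile curves and quantile differences
    combines subject-block bootstrap standard errors with a wild-bootstrap
    bias adjustment that resamples estimated random effects. Includes a
    synthetic-data generator with known quantile structure, model comparison
    via an extended log-F AIC with an effective-degrees-of-freedom partition,
    and a command-line interface over the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    splines,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
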