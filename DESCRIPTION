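Package: robustnorm
Title: Reaction Norm Models and Validation of Robustness Breeding Values
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Quantitative-genetic analysis of robustness of growth across
    environments in livestock. Derives an environmental covariable (EC) from
    contemporary-group post-weaning growth, fits linear reaction-norm mixed
    models by restricted maximum likelihood (pedigree, genomic or single-step
    relationships, heterogeneous residual variance along the EC), computes
    intercept, slope and scale-corrected slope breeding values with prediction
    error variances, and validates robustness breeding values by threefold
    cross-validation, forward prediction and between-dataset sire comparisons.
    Includes a synthetic-population generator with the matching variance
    structure for end-to-end testing of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
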