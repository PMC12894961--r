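Package: hsrtrait
Title: Leaf Trait Prediction from Hyperspectral Reflectance with Nested
    Cross-Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric pipeline for predicting leaf structural, biochemical
    and physiological traits from hyperspectral reflectance (HSR) spectra.
    Implements partial least squares regression (NIPALS, from scratch) and
    linear-kernel support vector regression; three strategies for selecting
    the PLSR number of components (repeated cross-validated MSE consensus,
    single-CV MSE, and PRESS over random train/test sub-samples); a nested
    cross-validation engine with genotype- and season-exclusive fold plans
    covering within-distribution generalizability and cross-genotype /
    cross-season transferability scenarios, guarded by a built-in leakage
    audit; season-comparison descriptive statistics (coefficients of
    variation, between-season Spearman correlation of genotype means,
    regional cross-season spectral correlations, Mantel permutation tests on
    spectral covariance matrices); and a multi-season synthetic spectra
    generator with genotype, season, plot and genotype-by-environment
    variance components for end-to-end validation without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    MASS,
    vegan,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
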