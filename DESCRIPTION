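Package: pecomics
Title: Seasonal Classification and Missing-Data Imputation for Cheese
    Fatty-Acid and Mineral Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for season-of-production analysis of Pecorino Romano PDO
    cheese fatty-acid (%FAME) and mineral concentration profiles in the
    presence of block-missing data. Implements probabilistic principal
    component analysis fitted by expectation-maximisation over arbitrary
    missingness patterns, linear discriminant classification of samples in
    latent-score space, partial least squares comparators (PLS-DA and PLS
    regression on the fully observed mineral block), a hybrid Monte-Carlo
    cross- plus external-validation protocol for model-order selection, Tukey
    honest-significant-difference comparisons computable from published
    summary statistics, and a synthetic-data generator reproducing the
    45 x 81 block-missing study design with season-dependent mean shifts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
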