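Package: sersga
Title: Genetic-Algorithm Band Selection and LDA Classification for Serum SERS Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A chemometric pipeline for two-class diagnostic analysis of serum
    surface-enhanced Raman spectroscopy (SERS) spectra. Provides iterative
    polynomial autofluorescence baseline correction, Savitzky-Golay smoothing
    and area normalization; a segment-encoded genetic algorithm that searches
    small subsets of spectral bands maximizing leave-one-out cross-validated
    linear-discriminant accuracy, with consensus band counting over repeated
    runs; Fisher LDA and PCA-LDA classifiers with LOOCV; ROC/AUC, per-band
    t-tests and difference spectra; and a synthetic two-class spectrum
    generator with planted diagnostic bands for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    signal,
    pracma,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
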