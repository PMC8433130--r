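Package: sersNGK
Title: Label-Free SERS Cell Classification with a Nonnegative Garrote
    Kernel Machine
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for classifying cells from label-free surface-enhanced
    Raman spectroscopy (SERS) spectra. Implements spectral preprocessing
    (substrate background subtraction, saturation-outlier rejection,
    peak-window intensity extraction over a selected Raman-shift panel),
    a nonnegative-garrote-on-kernel-machine (NGK) binary classifier with
    per-wavenumber variable selection, repeated stratified 10-fold
    cross-validated pairwise discrimination with five-number summaries,
    and blind-group assignment by two-sample t statistics. Includes a
    seeded synthetic SERS-spectrum generator so the whole pipeline is
    testable without measured spectra, and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
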