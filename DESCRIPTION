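Package: ramanpls
Title: Generic Chemometric Calibration Models for Raman Bioprocess Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building transferable ("generic") chemometric calibration
    models from Raman spectra of mammalian cell cultivations. Provides wavenumber
    standardization by cubic-spline interpolation onto a common grid,
    Savitzky-Golay first-derivative plus standard-normal-variate preprocessing,
    NIPALS partial least squares (PLS1) regression with batch-grouped
    cross-validated latent-variable selection, and standard figures of merit
    (RMSE, R-squared, SEC/SEP as percent of the reference range). Includes a
    seeded synthetic-data generator emulating a multi-site, multi-instrument
    fed-batch calibration corpus, an external dilution-series validation set,
    and an independent culture run, so the full calibration-transfer workflow
    can be exercised end to end without proprietary spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
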