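Package: photostab
Title: Photostability of 1,4-Dihydropyridines by Curve Resolution and QSPR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric pipeline for assessing the photostability of
    1,4-dihydropyridine drugs from UV spectral time series. Resolves
    irradiation series into component concentration profiles and pure
    spectra by constrained multivariate curve resolution - alternating
    least squares (non-negativity, unimodality, closure), estimates
    first-order photodegradation rate constants and t0.1 stability times,
    and relates the rates to molecular descriptors through quantitative
    structure-property (QSPR) regression with forward variable selection,
    leave-one-out cross-validation, principal component regression and
    PCA exploration. Ships the published descriptor and kinetics tables
    for a set of thirty hexahydroquinoline-type dihydropyridines together
    with a synthetic-data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
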