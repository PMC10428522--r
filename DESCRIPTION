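Package: specres
Title: Spectral Resolution of Overlapping Binary Mixtures by Ratio and
    Derivative Spectrophotometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for resolving and quantifying binary drug mixtures with
    severely overlapping UV absorption spectra. Implements nine
    spectrophotometric routes built from ratio-spectrum algebra: ratio
    subtraction, constant multiplication and factorized-spectrum methods
    coupled with spectrum subtraction on zero-order and first-derivative
    spectra, the first derivative of ratio spectra, and the constant-value
    and concentration-value plateau methods. Includes linear calibration
    with detection limits, method-validation statistics (recovery,
    precision, t/F tests, single-factor ANOVA), a Beer-Lambert
    Gaussian-band spectrum simulator for the triclabendazole/levamisole
    overlap, and greenness scoring by NEMI quadrants, the Analytical
    Eco-Scale and AGREE.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
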