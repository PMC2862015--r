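Package: zveec
Title: Acoustic Estimation of the Upper Limit of Oxygen Minimum Zones
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate the upper boundary of an oxygen minimum zone
    (OMZ) from the vertical extension of the epipelagic community observed
    with bi-frequency (38/120 kHz) scientific echosounders. Implements
    range-dependent noise modelling and linear-domain subtraction,
    resampling of echograms to common elementary cells, dB-difference
    discrimination of fish from other scatterers, the weighted
    98%-cumulative-backscatter depth statistic (Z_VEEC), oxycline feature
    extraction from dissolved-oxygen profiles, station matching and
    regression-based validation, habitat-volume integration over a
    horizontal mask, Morlet continuous wavelet analysis of the resulting
    space series, and a synthetic-survey generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    geosphere,
    interp,
    jsonlite,
    ncdf4,
    pracma,
    RcppTOML,
    sp,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
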