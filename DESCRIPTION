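Package: pactcal
Title: Geometric Calibration of Ultrasound Transducer Arrays for
    Photoacoustic Computed Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the three-dimensional positions of the individual
    elements of an ultrasound transducer array from point-source
    time-of-arrival data, as used to calibrate photoacoustic computed
    tomography (PACT) systems. Pairwise differencing of squared
    time-of-arrival relations yields a linear system per transducer that is
    solved by the pseudo-inverse. Includes the supporting time-of-arrival
    estimator (maxima-aligned averaging with a noise-threshold first
    arrival), speed-of-sound inference from water temperature, least-squares
    error propagation for point-source grid design, a band-limited synthetic
    data simulator, universal back-projection reconstruction, and
    image-quality metrics (CNR, covariance-based size and spread, FWHM).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
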