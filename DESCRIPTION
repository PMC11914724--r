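Package: ecgrisk
Title: Mortality Risk from 12-Lead ECGs as Signals, Paper Images, and Digitized Traces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for predicting time to mortality from
    12-lead electrocardiograms along three routes: natively digital 1D
    signals, digitized signals recovered from paper-format ECG images, and
    direct 2D image input. Includes a seeded synthetic ECG generator with
    linked survival outcomes, a paper-format renderer (4x3 layout with
    optional rhythm strips, grid, and scan degradation), a grid-calibrated
    digitization pipeline, shared signal preprocessing (band-pass, notch,
    resampling, power-of-two padding, asynchronous lead masking), small
    discrete-time survival convolutional networks (1D residual and 2D),
    and evaluation utilities (round-trip digitization fidelity, Harrell's
    concordance index with bootstrap intervals).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    png,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
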