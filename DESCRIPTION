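Package: lamline
Title: Depth-Resolved Analysis of Line-Scanning fMRI Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing laminar (cortical-depth resolved) BOLD
    responses measured with line-scanning fMRI. Implements forward
    population-receptive-field modelling with divisive normalization for
    participant-specific stimulus design (size tuning, annulus geometry,
    checkerboard rendering), a seeded generator of synthetic line-scanning
    sessions with known laminar ground truth, preprocessing (multi-echo
    combination, Savitzky-Golay smoothing, percent-signal-change scaling,
    event-related epoching, gray-matter re-gridding to a standard 20-point
    depth grid), template-weighted depth-profile extraction, and a
    descriptive laminar model (double Gaussian plus derivatives with a
    draining-vein term) summarised by a contextual beta statistic, with
    unidirectional-drainage forward and inverse (deconvolution) operators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
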