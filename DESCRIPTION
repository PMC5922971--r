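Package: tactcode
Title: Coincidence Coding by Tactile Afferent Subfields and
    Pointer-Alignment Trial Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates populations of first-order tactile neurons innervating a
    virtual fingertip skin patch, with receptive fields composed of either many
    small receptor elements (subfields) or a single uniform receptive element,
    and measures edge-orientation discrimination thresholds of the population
    under a binary coincidence code (Hamming-distance criterion over activation
    vectors during edge rotation).  Also provides an event-detection pipeline
    for 1 kHz force and dial-orientation traces from tactile pointer-alignment
    trials (touch detection, force-plateau detection, triangular FIR filtering,
    rotation-velocity peak finding, sub-movement segmentation, alignment-error
    and direction summary statistics), together with a synthetic trial
    generator that emulates the statistical structure of such trials and
    carries ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tibble,
    dplyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
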