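Package: frptools
Title: Fixation-Related Potential Analysis for Co-Registered EEG and Eye Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing co-registered electroencephalography (EEG) and
    eye-tracking recordings from naturalistic visual search tasks. Implements
    dispersion-based fixation detection, affine clock resynchronization between
    recording modalities, EEG filtering and ICA-based artifact-component
    rejection, time-independent gaze-pattern difficulty metrics with Fisher
    discriminant classification, single-trial P100 amplitude estimation on
    fixation-locked epochs via multiple linear regression with dispersion
    terms (MLRd), and relative-bandpower classification of action versus
    exploratory fixations. Ships a synthetic session generator that emulates
    a two-by-three visual search design (object count by color similarity),
    fixation-locked evoked components, keypress-locked slow activity, and
    inter-modality clock error, so the full pipeline is testable without
    access to recorded subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr
Config/testthat/edition: 3
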