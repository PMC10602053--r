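Package: sleepkit
Title: Sleep EEG/EMG, Phasic REM, and Calcium-Imaging Analysis for Rodent Polysomnography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for rodent sleep-physiology recordings: hypnogram
    handling and episode segmentation, Welch spectral analysis and band powers,
    closed-loop REM-sleep detection from theta/delta ratios, phasic theta event
    detection from Hilbert-phase trough intervals, heart-rate extraction from
    R-waves embedded in the nuchal EMG, pupillometric rapid-eye-movement
    detection, bootstrap statistics on laser-aligned brain-state transition
    probabilities, and fiber-photometry/miniscope calcium-imaging pipelines
    (motion correction, activity maps, neuropil-corrected dF/F, brain-state
    subclass classification). Includes a full synthetic-data generator with
    ground-truth ledgers so every stage can be validated without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
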