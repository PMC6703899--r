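Package: sleepscope
Title: Sleep-State and Cataplexy Analysis of Miniscope Calcium Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for single-cell calcium imaging recorded
    alongside EEG/EMG sleep scoring in narcoleptic and control mice.
    Normalizes fluorescence traces to dF/F and per-cell Z-scores, scores
    4-second epochs into wake/sleep states, applies rule-based cataplexy
    validation with spontaneous versus emotion-induced subtyping, classifies
    state-tuned ("ON") neurons against a quiet-wake baseline, detects
    prominent calcium transient peaks, quantifies pairwise Fisher-Z
    synchrony and spatial connectivity, and builds time-normalized
    transition activity profiles. Includes a synthetic-session generator
    with known ground truth for validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
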