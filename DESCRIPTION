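Package: ssvepbench
Title: Training-Free SSVEP Detection and Pseudo-Online Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing steady-state visually evoked potential (SSVEP)
    frequency recognition in brain-computer interface experiments. Implements
    three training-free detectors (canonical correlation analysis, filter-bank
    CCA, and minimum energy combination spatial filtering), segment-averaged
    power spectral density and wide-band signal-to-noise ratio estimation,
    stimulation-versus-baseline channel-frequency contrast maps, and a
    pseudo-online sliding-window evaluation layer reporting detection
    accuracy, detection time, and information transfer rate. A synthetic
    multi-channel EEG session generator with the standard run/trial/phase
    layout makes the whole pipeline testable end to end without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    tibble,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
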