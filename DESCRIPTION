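Package: laparosound
Title: Acoustic Characterization and Channel-Adapted Classification of
    Electrosurgical Sounds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing how acoustic adapters mounted on
    laparoscopic trocars alter electrosurgical (diathermy) sound, and for
    adapting a spectrogram classifier to those channels. Implements
    maximum-length-sequence (MLS) impulse-response estimation by circular
    cross-correlation, transfer functions and dB-valued relative transfer
    functions with fractional-octave Savitzky-Golay smoothing, acoustic
    channel simulation by impulse-response convolution, a 96x64 log-mel
    spectrogram front end, recording-level dataset balancing and
    splitting, a compact trainable classifier with grid search and
    channel-specific fine-tuning, and macro precision/recall/F1
    evaluation. Includes a synthetic-data module that generates labelled
    tissue-sound surrogates and synthetic adapter impulse responses so
    the whole pipeline runs end to end without recorded data.
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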