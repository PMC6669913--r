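Package: erpbci
Title: Auditory Oddball ERP Brain-Computer Interface Analysis for
    Prefrontal Single-Channel EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis pipeline for auditory oddball
    event-related potential (ERP) brain-computer interfaces recorded from a
    single prefrontal EEG channel at 512 Hz. Builds randomized five-sound
    stimulus schedules and spatializes mono stimuli via interaural time and
    level differences; simulates single-channel recordings with
    subject-specific N200/P300 templates and 1/f background noise; extracts
    baseline-corrected one-second epochs, band-pass filters, screens
    artifacts and downsamples to 16 features; classifies with stepwise
    linear discriminant analysis (SWLDA, p<0.10 entry / p>0.15 removal);
    and evaluates via leave-one-trial-out cross-validation,
    reduced-command sweeps, confusion matrices, Wolpaw information
    transfer rate, signed R-squared discriminability and incremental
    learning curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'erpbci-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'paradigm.R'
    'wav.R'
    'edf.R'
    'synth.R'
    'preprocess.R'
    'swlda.R'
    'evaluate.R'
    'reference.R'
    'io.R'
    'pipeline.R'
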