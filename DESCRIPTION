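Package: ptfm
Title: Acoustic Mass Sensing with a Piezoelectric Thin-Film Microbalance
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models, simulates and analyses a piezoelectric thin-film
    microbalance (PTFM) that reports adsorbed micro-mass through shifts of
    its acoustic resonance. Provides the closed-form frequency-mass
    relations (Sauerbrey and thin-film variants, theoretical and empirical
    mass sensitivity, quality-factor/bandwidth analysis), a seeded
    synthetic-signal generator emulating the driven resonator captured as
    48 kHz audio, spectral and patch featurisation, three trainable
    classifiers (1-D CNN, LSTM and transformer encoder) for ten mass-load
    classes, evaluation metrics with confusion matrices and architecture
    sweeps, and linear frequency-shift calibration with mass inversion.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'constructors.R'
    'physics.R'
    'simulator.R'
    'features.R'
    'nn-engine.R'
    'models.R'
    'train-eval.R'
    'calibration.R'
    'wav.R'
    'cli.R'
    'ptfm-package.R'
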