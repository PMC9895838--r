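Package: mTRFknee
Title: Training-Data Sufficiency Analysis for EEG Temporal Receptive Field Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for deciding how much training data a multivariate temporal
    receptive field (mTRF) EEG encoding model needs. Implements ridge regression
    on time-lagged stimulus designs with cross-validated regularization,
    incremental-training-size bootstrap learning curves, curvature-based
    knee-point detection on the performance curve, and adjacent-weight stability
    analysis. Includes a synthetic-data generator with known ground-truth
    receptive fields, speech stimulus feature computation (acoustic envelope,
    pitch ingestion, binary phonological onset matrices), EEG preprocessing
    (zero-phase FIR band-pass, notch, polyphase resampling), and audio-to-EEG
    alignment by matched filtering.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    signal,
    jsonlite,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'annotations-io.R'
    'audio-io.R'
    'synthdata.R'
    'dataset-io.R'
    'encoding.R'
    'features.R'
    'mTRFknee-package.R'
    'sufficiency.R'
    'pipeline.R'
    'preprocess.R'
    'resample.R'
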