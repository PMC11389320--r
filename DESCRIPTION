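Package: catse3
Title: Composite Activity-Type and Stride-Specific Energy Expenditure
    Estimation for Thigh-Worn Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the CATSE3 composite pipeline for estimating
    activity-related energy expenditure from raw thigh-worn triaxial
    accelerometry: signal preprocessing (zero-phase Butterworth filtering,
    gravity autocalibration, uniform resampling, 4-second epoching),
    five-class activity classification with a hybrid convolutional /
    bidirectional-LSTM network, activity-specific stride segmentation with
    Fourier time-normalisation, a temporal convolutional network for
    stride-level energy expenditure, linear ENMO/MAD baseline models,
    indirect-calorimetry reference computation via the Weir equation, a
    validation metric suite (classification metrics, RMSE, MAPE, R-squared,
    Bland-Altman limits of agreement), and a synthetic-data generator that
    emulates the laboratory activity protocol so the whole pipeline is
    trainable and testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    tools,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
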