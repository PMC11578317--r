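Package: ppgglucose
Title: Non-Invasive Blood Glucose Estimation from Photoplethysmography
    Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for estimating blood glucose from
    fingertip photoplethysmography (PPG) waveforms: a synthetic waveform
    generator with a known glucose-to-morphology link, beat segmentation
    anchored at the trough of the first double-peak pulse, fiducial-point
    detection (systolic peak, dicrotic notch, diastolic peak, bottom),
    an eleven-feature summary per recording, a from-scratch
    gradient-boosted regression-tree model with residual boosting plus
    classical baselines, and a clinical evaluation surface covering
    MARD, RMSE, MAE, R-squared, the 1987 Clarke Error Grid, Monte Carlo
    cross-validation, and aleatoric/epistemic uncertainty estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
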