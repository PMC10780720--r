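Package: fepoch
Title: Floating-Epoch Analysis of Raw Accelerometry for Oxygen Uptake Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Processes raw hip-worn triaxial accelerometer data (100 Hz, g
    units) into stride-adaptive "floating epoch" features for estimating
    oxygen consumption (VO2) during walking. Implements the fixed-point
    recursive filters (0.12 Hz baseline low-pass, 12 Hz Butterworth low-pass,
    1-3 Hz Butterworth band-pass), zero-crossing step segmentation with
    +/-0.05 g hysteresis, per-step and floating-epoch mean amplitude
    deviation (MAD), dMAD and step-frequency features, the conventional
    fixed 6 s epoch MAD baseline, bundled linear VO2 prediction equations,
    ordinary least squares refitting with agreement statistics (bias,
    SEE, R2, MAPE, Bland-Altman limits of agreement), and a synthetic gait
    generator for constant-speed and shuttle-walk protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
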