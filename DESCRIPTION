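Package: scopeflow
Title: Colonoscope Movement Analysis and Cecum Time-Location from Video Frames
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyzes colonoscopy videos sampled as frame sequences to recover
    the direction of colonoscope movement and the time-location of the cecum.
    Computes Horn-Schunck optical flow between consecutive frames, encodes the
    flow field as a color image (hue for direction, saturation for magnitude),
    classifies flow-color images into insertion, withdrawal and stop with a
    small convolutional neural network trained by stochastic gradient descent
    with randomized hyperparameter search, filters non-informative frames with
    a seven-feature support-vector classifier, detects the cecum as the
    insertion-to-withdrawal turning point whose windowed signed graph area is
    minimal, and renders color-coded timeline summary reports. Includes
    synthetic-data generators (textured frame pairs under known motion,
    degraded frames, direction-label signals with known cecum time) used as
    ground truth throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    png,
    e1071,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
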