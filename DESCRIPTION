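Package: bootgait
Title: Wearable IMU Monitoring of Achilles Tendon Load and Walking Speed
    During Immobilizing-Boot Gait
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating peak Achilles tendon load and walking speed
    from body-worn inertial measurement units (IMUs) while walking in an
    immobilizing orthopaedic boot. Provides a seeded synthetic gait-trial
    generator with known ground truth, insole-force gait event detection
    (50 N threshold) and stride segmentation, stride-level IMU feature
    extraction (extrema and phase impulses for all six channels), per-stride
    tendon-load and per-trial walking-speed targets with a 0.5 body-weight
    inclusion filter, L1-regularized (LASSO) regression with leakage-safe
    standardization, and evaluation under generalized (leave-one-subject-out),
    hybridized, and personalized training paradigms, including sensor
    ablations (gyroscope removal, 50/25 Hz decimation, multi-sensor
    configurations), learning curves, and cross-correlation sensor agreement.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
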