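Package: camsens
Title: Regional Importance Mapping of Nodule Classifiers via Class
    Activation Maps and Adversarial Perturbation
Version: 0.1.0
Authors@R:
    person("camsens", "maintainers", email = "camsens@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying which sub-nodular regions of an
    ultrasound image drive a convolutional classifier's malignancy
    prediction. Implements class activation maps (CAM) for global
    average pooling classifiers, malignancy-probability-scaled heat
    maps, equal-area concentric level-set partitioning of nodular
    CAMs, region-restricted fast gradient sign method (FGSM)
    perturbation with AUC-gradient noise calibration, and the full
    statistical evaluation protocol (ROC/AUC, DeLong's paired test,
    subset splits with paired t-tests, Dice overlap, and
    frequency-weighted ACR TI-RADS feature scoring). Ships a seeded
    synthetic B-mode ultrasound nodule phantom with localized
    malignancy cues and a small CPU-trainable stand-in classifier so
    that every experiment runs end-to-end without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
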