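Package: stvqt
Title: Beat-to-Beat Variability of Repolarization on the Multi-Lead ECG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies short-term beat-to-beat variability of the QT
    interval (STVQT, also called beat-to-beat variability of
    repolarization, BVR) on multi-lead electrocardiograms, as used to
    track repolarization lability during acute myocardial ischemia.
    Provides a synthetic 12-lead ECG generator with analytically known
    per-beat QT ground truth, fiducial-segment-averaging QT measurement
    with tangent-method T-wave end detection, premature-ventricular-complex
    classification and exclusion rules, per-segment repolarization metrics
    (BVR, QT dispersion, ST-segment deviation, heart rate), study-design
    orchestration for occlusion/pre-fibrillation time points and pre-VF
    surge detection, a sampling-rate sensitivity experiment, and a
    programmed-electrical-stimulation arrhythmia-inducibility index.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    signal,
    data.table,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
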