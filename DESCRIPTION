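Package: fluorMargin
Title: Fluorescence-Guided Assessment of Lumpectomy Cavity Margins
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for intraoperative
    protease-activated fluorescence imaging of lumpectomy cavity margins.
    Generates synthetic cavity-margin fluorescence images with known
    ground-truth histopathology, applies injection-timing and probe-contact
    quality control, calibrates per-patient detection thresholds from a
    pooled normal-tissue-baseline coefficient selected on a receiver
    operating characteristic curve, classifies margin surfaces against the
    per-patient threshold, adjudicates device readings against
    histopathology (shaved-specimen arbitration, on-ink and 2-mm margin
    rules), and summarises cohort-level sensitivity, specificity,
    tumor-to-normal signal ratios, and clinical-outcome accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    jsonlite,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
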