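Package: dcisgrade
Title: Automated Grading of Ductal Carcinoma In Situ in Breast Histopathology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end toolkit for automated grading of ductal carcinoma in
    situ (DCIS) lesions from annotated H&E histopathology images. Reads
    polygon lesion annotations (ASAP XML dialect) and multi-observer grade
    tables, builds consensus training targets (majority vote with a
    three-way-split rule) together with the observer agreement count,
    extracts lesion crops at a working magnification with a stromal border
    and samples fixed-size patches with stain-appearance augmentation, trains
    a dual-head convolutional grade classifier, aggregates patch predictions
    to lesion grades (10-patch median) and lesion grades to patient grades
    (nearest-rank percentile), and evaluates agreement between graders with
    quadratic weighted Cohen's kappa and analytic confidence intervals. A
    synthetic cohort generator renders grade-dependent duct images with
    simulated noisy observers so the whole pipeline can be exercised and
    validated without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
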