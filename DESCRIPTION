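Package: lesioneval
Title: Low-Bias Evaluation of Computer-Aided Colorectal Lesion Detection
Version: 0.1.0
Authors@R:
    person("lesioneval", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Evaluation pipeline for video-based computer-aided detection
    (CADe) of colorectal lesions. Samples still frames from annotated
    colonoscopy streams at fixed intervals, applies standard exclusion
    criteria, and computes image-level diagnostic performance (sensitivity,
    specificity, PPV, NPV, accuracy with exact Clopper-Pearson confidence
    intervals), ROC curves over a fixed threshold grid with trapezoidal AUC
    and Youden-index cutoff selection, and bounding-box localization
    accuracy via intersection over union. Includes the display-side 3-of-5
    sequential-frame persistence filter, per-lesion detection-latency
    analysis with a timeout failure rule, and a synthetic detector-output
    generator so the whole pipeline is testable without endoscopy data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
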