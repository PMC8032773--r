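Package: escadet
Title: Temporal Confirmation and Evaluation of Video-Based Esophageal Cancer Detection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Decision layer for video computer-aided detection (CADe) of
    superficial esophageal squamous cell carcinoma in endoscopy screening.
    Implements the frame-vote discovery-signal confirmation rule that turns
    noisy per-frame detector output into per-lesion alarms, matching of
    alarms against ground-truth lesion visibility, per-video diagnostic
    accuracy metrics (sensitivity, specificity, PPV, NPV) under white-light
    and narrow-band imaging with either-modality union analysis,
    time-to-detection summaries, false-positive and false-negative cause
    tabulation, reader-study scoring, and exact McNemar and Mann-Whitney
    tests. A seeded simulator generates realistic paired detection streams
    emulating constant-speed esophageal traversal in place of a trained
    detector network.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
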