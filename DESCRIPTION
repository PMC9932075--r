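Package: ethocoder
Title: Frame-Wise Animal Behavior Classification with Confidence-Based Review
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A pipeline for automated per-frame classification of animal
    behavior in laboratory video. Appearance and motion are encoded with a
    two-stream approach: raw frames and dense TV-L1 optical flow rendered as
    color images are passed through a convolutional backbone to give
    512-dimensional per-frame features, which are concatenated across streams
    and cameras, reduced with reconstruction independent component analysis,
    and classified frame-by-frame with a two-layer bidirectional LSTM.
    Softmax- and temperature-scaled confidence scores are aggregated to clip
    level to estimate annotation quality without ground truth, and a review
    framework quantifies how efficiently low-confidence-first review recovers
    dataset accuracy relative to random and accuracy-sorted orderings.
    Includes seeded synthetic generators (videos, Markov label processes,
    class-conditional features, calibrated logits) so the full pipeline is
    testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
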