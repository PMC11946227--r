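Package: cowgait
Title: Lameness Scoring for Dairy Cows from Walking Keypoint Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Turns tracked walking keypoints of dairy cows (one head landmark
    and three back landmarks) into a 0-3 lameness score. Reads pose-tracker
    keypoint tables, cleans low-confidence frames, computes the two
    feature-triangle vertex angles over the back via the law of cosines,
    compares each bout's angle distribution against a normal-cow reference
    interval, and maps the resulting overlap coefficients through a banded
    scoring model to a four-level lameness grade. Includes a seeded synthetic
    gait generator with an exact geometry inverter so the whole pipeline is
    testable without video, plus keypoint-error and grade-accuracy evaluation
    and a k-means representative-frame selection utility.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
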