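Package: smoltroutes
Title: Migration-Route Classification and Survival Modelling for Acoustic
    Telemetry Receiver Curtains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing detections of acoustically tagged juvenile
    salmonids (smolts) at large receiver "curtain" arrays. Collapses raw
    detections into detection sequences, classifies migration routes
    (linear, counterclockwise, clockwise) from east-west displacement
    between sequences, computes lateral displacement and residence
    metrics, runs the associated descriptive and hypothesis-test battery,
    and fits binomial survival models with all-subsets enumeration,
    AICc ranking and multi-model averaging. Includes an agent-based
    synthetic telemetry generator with per-smolt ground truth for
    validating the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
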