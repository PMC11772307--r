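Package: turtlehr
Title: Non-Invasive Heart-Rate Analysis for Sea-Turtle Biologging Deployments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating heart rate of sea turtles from
    animal-borne electrocardiogram (ECG) and accelerometer loggers. The
    pipeline band-pass filters the ECG, detects R waves with an adaptive
    windowed-quantile threshold and refractory rule, grades signal quality
    on a three-level scale, classifies per-minute resting/moving behaviour
    from the standard deviation of longitudinal acceleration, segments
    minimum-duration phases, excludes a post-handling window, and computes
    phase-conditioned heart-rate statistics. A synthetic deployment
    generator with known ground truth (true R-wave times, true minute
    statuses) makes every stage verifiable without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
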