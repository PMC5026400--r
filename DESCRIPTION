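Package: sowmotion
Title: Posture States and Posture Transitions in Farrowing Sows from
    Hind-End Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies the lying behaviour of farrowing sows from a single
    tri-axial accelerometer mounted on the hind-end. Estimates the static
    (gravity) component of the signal with a recursive smoothing filter,
    derives per-frame pitch, roll and activity features, detects and segments
    posture transitions with a thresholded extended-frame rule, classifies
    the five posture states (standing, sitting, left/right lateral lie,
    sternal lie) with a radial-basis-function support vector machine under
    leave-one-pig-out cross-validation, extracts kinematic descriptors of
    each transition (duration, peak acceleration, acceleration range, jerk,
    pitch/roll rates), and summarises per-animal behaviour as posture time
    budgets, transition-frequency series and empirical cumulative
    distribution functions of the transition features. Includes an
    event-based precision/recall evaluation against interval annotations and
    a semi-Markov sow-motion simulator that provides ground-truth traces for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
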