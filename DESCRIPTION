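Package: standup
Title: Hindlimb Kinematics, Kinetics and Muscle Dynamics of the Canine
    Sit-to-Stand Transition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for analysing the sit-to-stand (StS)
    transition of a quadruped hindlimb: marker-cluster kinematics (rigid
    Procrustes pose fitting, Y-X'-Z'' Cardan decomposition, zero-phase
    Butterworth filtering, gap filling, outlier screening and time
    normalisation), force-plate processing with bilateral splitting and a
    foot-midline centre of pressure, Newton-Euler inverse dynamics of a
    four-segment pelvis-thigh-shank-foot chain, and muscle-redundancy
    resolution by static optimization with a rigid-tendon Hill muscle
    model, reserve actuators, tendon-slack-length calibration and
    sensitivity analyses. Ships a dissection-based greyhound hindlimb
    muscle architecture table and a synthetic StS trial generator so every
    stage can be exercised and validated without motion-capture data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
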