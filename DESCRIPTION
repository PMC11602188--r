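Package: stickreach
Title: Simulation and Analysis of Bimanual Stick-Reaching Adaptation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying visuomotor adaptation in a kinematically
    redundant bimanual task in which a virtual stick held with both hands is
    used to reach targets with the stick tip. Provides the stick kinematics,
    a minimum-hand-path-cost model predicting the baseline relationship
    between tip-movement direction (TMD) and stick-tilt angle (STA),
    end-effector relevant and irrelevant visual perturbation regimes, a
    trial-by-trial state-space learner in which visual errors are corrected
    along the baseline TMD-STA relationship, minimum-jerk trial synthesis,
    kinematic analysis (zero-phase Butterworth filtering, peak-velocity
    read-outs, trial segmentation, variability), and a synthetic-study
    generator with heterogeneous participant populations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
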