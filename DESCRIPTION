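Package: exotwin
Title: Digital Twin of a Force-Feedback Cranial Exoskeleton for Mice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale digital twin of a head-mounted robotic exoskeleton
    that lets mice steer a delta parallel robot and motorized goniometer by
    force feedback. Implements the robot's geometric kinematics, lumped-mass
    inverse dynamics and motor feasibility checks, the discrete-time
    admittance controller with dead-band and velocity limits, oval-track and
    figure-8 maze task logic (trajectory servoing, turning-zone limits,
    cue/reward events), a frequency-domain loop model for apparent-admittance
    bandwidth, a stochastic virtual-mouse locomotion generator, and the
    downstream analysis pipelines: filtered kinematics and peak statistics,
    admittance-plane fitting, turn scoring, gait extraction, Clopper-Pearson
    intervals, calcium dF/F and spike-rate preprocessing, and place-field
    kernel regression (pseudoinverse and reduced-rank).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
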