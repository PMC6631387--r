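Package: mapdyn
Title: Floating-Base Maximum-A-Posteriori Estimation of Whole-Body
    Kinematics and Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simultaneous stochastic estimation of whole-body link
    accelerations, external wrenches, joint wrenches, joint accelerations
    and joint torques for articulated floating-base models (for example a
    human instrumented with distributed IMUs and force/torque sensorized
    shoes).  Provides spatial (6-D) vector algebra and a URDF-subset
    multi-body model reader, a recursive Newton-Euler inverse-dynamics
    oracle, offline least-squares calibration of sensor positions,
    link-pairwise inverse kinematics with Savitzky-Golay differentiation,
    contact-constrained base-velocity estimation, vertical-force contact
    classification, a sparse Gaussian maximum-a-posteriori solver for the
    stacked dynamics/measurement system, and a rigid-body-consistent
    synthetic data simulator for testing every stage without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    graphics,
    xml2
Suggests:
    optparse,
    signal,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
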