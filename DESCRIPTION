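Package: mousegait
Title: Dynamic Simulation of Mouse Hindlimb Trotting
Version: 0.1.0
Authors@R:
    person("Biomechanics", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for dynamic simulation of the mouse hindlimb
    during trotting locomotion: a Hill-type musculotendon-unit (MTU)
    musculoskeletal model of the hindlimb and pelvis, marker and force-plate
    gait processing (zero-phase Butterworth filtering, cubic-spline stride
    pooling with 95% confidence intervals), inverse dynamics on the sagittal
    linkage, static optimization resolving net joint moments into muscle
    activations with reserve and residual actuators, muscle-driven forward
    dynamics with first-order activation dynamics and coordinate limit
    forces, and musculotendon mechanical-work analysis with functional
    classification of each actuator as a motor, brake, strut or spring.
    A synthetic trotting-gait generator reproduces the statistical structure
    of published mouse gait data so that every stage is testable without
    laboratory recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
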