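Package: snapmech
Title: Biomechanics of Power-Amplified Termite Mandible Snaps
Version: 0.1.0
Authors@R:
    person("Snapmech", "Developers", email = "maintainer@snapmech.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for the asymmetric mandible snap of termite
    soldiers: two-point-mass moment-of-inertia estimation for the rotating
    anterior left mandible, rigid-body snap kinematics (tip velocity, angular
    acceleration, force, energy) from ultrahigh-speed angular measurements,
    energy-conservation inversion of ball-strike experiments into snap energy
    and tip velocity, digitized-track calibration, strike-angle precision
    statistics, and ant-defence contingency analysis with pairwise Fisher
    exact tests under Bonferroni correction. Includes a seeded synthetic-data
    generator that forward-simulates every input table with known ground
    truth, and a configurable end-to-end cohort report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
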