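Package: prehension
Title: Anticipatory Torque Control Analysis for Precision-Grip Lifting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for precision-grip object-lifting experiments
    that probe anticipatory motor control. Builds pre/post-switch trial
    schedules, simulates physically consistent digit force, torque and object
    kinematic recordings for an asymmetrically weighted T-shaped manipulandum,
    filters and differentiates the raw channels, detects reach/grasp/lift
    events, computes per-trial compensatory torque and its lift-force and
    digit-placement components together with grip-lift rate coupling, and runs
    the group-level mixed-design ANOVAs with partial eta squared and
    Bonferroni-corrected pairwise comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
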