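Package: texdisc
Title: Virtual-Texture Discrimination: Haptic Rendering, Triangle-Test
    Protocols and Psychometric Reliability Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulation and analysis toolkit for robot-rendered
    texture-discrimination experiments. Implements sinusoidal-grating haptic
    force rendering with a virtual table and cycloidal robotic guidance,
    triangle-test constant-stimuli trial generation, simulated observers with
    known psychometric sensitivity, logistic psychometric-function fitting with
    point-of-subjective-equality (PSE) outcomes and PSE-adaptive training
    stimulus construction, kinematic exploration outcomes, exact-binomial
    triangle-test power and sample-size computation, and ICC(2,k) /
    Bland-Altman test-retest reliability statistics. A seeded protocol
    simulator runs the full three-session assessment/training study with
    simulated participants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
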