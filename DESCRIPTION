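Package: spinegrowth
Title: Patient-Specific Finite-Element Simulation of Scoliotic Curve Progression
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building patient-specific finite-element models of the
    adolescent thoracolumbar spine and simulating multi-year scoliotic curve
    progression under stress-modulated vertebral growth (Hueter-Volkmann law).
    Includes biplanar landmark triangulation, a parametric hexahedral
    template of the T1-L5 osteo-ligamentous spine, dual-kriging mesh morphing,
    age- and flexibility-scaled material assignment, a small-strain linear
    elastic solver with eigenstrain growth loading and tension-only ligament
    springs, a two-pass anti-gravity loading protocol, automated extraction of
    clinical spine-curvature indices (Cobb, kyphosis, lordosis, axial rotation,
    vertebral wedging), and a synthetic-patient generator with prescribed
    curvature for testing and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    digest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
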