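Package: elbowmbs
Title: Multibody Simulation of Elbow Medial Collateral Ligament Deficiency
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Rigid multibody simulation of passive elbow flexion under
    graded medial collateral ligament (MCL) deficiency. Provides a seeded
    parametric elbow geometry generator (trochlea, capitellum, sigmoid
    notch, radial head, cartilage layers, ligament attachment atlas),
    discretized-cartilage Hertzian contact with penetration-dependent
    smoothstep damping and elastic-foundation stiffness estimation,
    nonlinear toe-region ligament bundles with wrapping around bone
    primitives, a quasistatic continuation solver for the prescribed
    humeral-head flexion drive, joint-coordinate-system kinematic
    decomposition, contact pressure mapping, and a scenario study
    comparing intact, isolated anterior-bundle, isolated posterior-bundle
    and complete MCL deficiency with one-way ANOVA and Tukey-Kramer
    pairwise statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    deSolve,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
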