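Package: premyoswarm
Title: Adapted Particle Swarm Model of Premyofibril Z-Body Patterning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates the self-organization of alpha-actinin clusters
    (z-bodies) along developing premyofibrils with an adapted particle swarm
    optimization algorithm. A swarm of candidate cluster configurations on a
    two-dimensional myofibril curve evolves under a Lennard-Jones pairwise
    energy with a stochastic cluster-recruitment step, producing regularly
    spaced punctate patterns. Includes fourth-order Bezier curve geometry with
    prescribed arclength and radius of curvature, spacing and uniformity
    metrics with random-pattern calibration, a parameter-grid ranking
    function, and seeded experiment drivers with ANOVA/Tukey group
    comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
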