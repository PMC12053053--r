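Package: acoustolev
Title: Acoustic Levitation Modelling and Alignment Statistics for Tissue Spheroids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale model of a bulk-acoustic-wave levitation chamber used to
    align 3D tissue spheroids in a hydrogel before sectioning. Solves the
    frequency-domain Helmholtz equation on the chamber with a displacement-driven
    transducer array and impedance walls, evaluates the Gor'kov acoustic radiation
    potential and force on sub-wavelength compressible spheres, integrates
    overdamped levitation trajectories to equilibrium, and analyses
    levitation-height distributions (Gaussian fits, slab-coverage metrics,
    two-sample Kolmogorov-Smirnov comparisons). A seeded synthetic-data generator
    emulates measured sedimented and levitated height populations so the analysis
    stage is testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
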