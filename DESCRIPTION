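Package: shuntfield
Title: Volume-Conductor Modelling of Scalp- and Skull-Applied Electrical
    Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing transcutaneous (scalp-applied) and
    subcutaneous (skull-applied) electrical brain stimulation in layered
    head phantoms.  Provides parameterized slab, concentric-shell and
    voxelized ellipsoid head models; a quasi-static finite-difference
    solver for the volume-conduction equation with electrode current
    injection, together with an analytic Legendre-series solution for
    N-shell spheres; the measurement chain from multi-channel subdural
    strip potentials to field gradients, per-milliamp slopes and scalp
    shunting ratios; calibration of scalp and skull conductivities
    against strip-field measurements; and pre/post-stimulation
    intracranial EEG band-power analysis with paired statistics.  All
    inputs can be generated synthetically with seeded generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    signal,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
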