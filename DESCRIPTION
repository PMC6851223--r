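Package: fibrecup
Title: Synthetic White-Matter Fiber Phantoms and Polarized Light Imaging Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction, transformation, bundle-filling and serialization of
    synthetic white-matter fiber models for polarimetric imaging simulations.
    Fiber trajectories are defined by parametric functions or cubic-spline
    interpolated control points; bundle envelopes are filled with child fibers
    seeded on a triangular grid and transported along the trajectory with
    Rodrigues-rotated frames. Includes a programmatic builder for a Fiber Cup
    style crossing phantom, fiber-fiber collision detection, HDF5 and plain-text
    serialization, and a Mueller-matrix 3D polarized light imaging (3D-PLI)
    forward simulator with a harmonic orientation-recovery stage producing
    color-coded fiber orientation maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rhdf5,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    png,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
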