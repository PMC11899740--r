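Package: selfguide
Title: Self-Guided Langevin and Molecular Dynamics with Spatial Averaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A self-contained molecular simulator implementing self-guided
    Langevin dynamics (SGLD) and self-guided molecular dynamics (SGMD).
    Low-frequency motion is extracted by exponential local time averaging and
    concerted motion by spatial averaging over bonded neighbourhoods or a
    trilinear particle-to-grid scheme; guiding forces built from these averages
    are applied in a leap-frog Langevin integrator with on-the-fly apparent
    friction estimation and a per-atom energy-conservation scaling factor.
    Includes a toy bead-spring force field, an implicit map-based boundary
    restraint box, seeded fixture generators, XYZ/PDB trajectory output and
    order-parameter diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    bio3d,
    yaml,
    tools,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
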