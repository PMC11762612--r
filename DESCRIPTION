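Package: pelvifem
Title: Finite-Element Comparison of Sacroiliac Screw Fixation for Fragility
    Fractures of the Pelvis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale finite-element pipeline for comparing unilateral
    sacroiliac (USI), bilateral sacroiliac (BSI) and transsacral (TSI) screw
    fixation of a type IIc fragility fracture of the pelvis. Provides a
    parametric voxel-lattice pelvis phantom with a synthetic Hounsfield-unit
    field, CT-style density and Young's-modulus material mapping (Dalstra
    power law) with material binning, the eight pelvic ligament groups as
    tension-only springs, a linear tetrahedral elasticity solver with tie
    constraints and an active-set iteration for tension-only elements, stance
    and validation load cases, and post-processing of fracture-gap distances
    and regional normal stresses, including a mesh-convergence protocol.
    Meshes and solutions round-trip through Gmsh MSH and VTK VTU text formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    xml2,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
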