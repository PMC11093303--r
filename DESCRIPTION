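Package: plexusfem
Title: Two-Dimensional Finite-Element Model of the Neonatal Brachial Plexus
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Parametric two-dimensional plane-stress finite-element pipeline
    for studying stretch loading of the neonatal brachial plexus (spinal cord,
    C5-T1 nerve roots, and the upper/middle/lower trunks). Builds the planar
    plexus geometry from published average infant dimensions, partitions a
    tensile load across trunks by composite theory, meshes the domain with
    structured bilinear quadrilaterals, solves the linear-elastic plane-stress
    problem with clamped-cord and guided-nerve boundary conditions, extracts
    von Mises stresses at the root-cord junctions and distal-trunk
    displacements and strains, and runs parametric sweeps over nerve-root
    angles. Includes analytic verification fixtures (uniform bar, distorted
    patch test, beam bending) and mesh-convergence utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
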