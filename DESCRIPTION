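Package: plexusflow
Title: Lattice-Boltzmann Haemodynamics of Microvascular Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates haemodynamic forces in microvascular networks such as
    the developing mouse retinal plexus. Provides skeleton-based
    three-dimensional vessel reconstruction and voxelization from binary
    vessel masks, a D3Q19 BGK lattice-Boltzmann solver for steady
    incompressible generalized-Newtonian flow with Bouzidi interpolated
    no-slip walls and pressure-drop boundary conditions, Carreau-Yasuda
    shear-thinning rheology fitted to murine viscometry data, wall-shear-stress
    post-processing with validity flagging, and an inclined-cylinder
    Hagen-Poiseuille validation suite with analytic flow-rate and
    stress-tensor references.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    igraph,
    jsonlite,
    yaml,
    EBImage,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    png,
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
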