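Package: memfence
Title: Particle-Based Simulation of Membrane Compartment Fences and Pickets
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Two-dimensional particle-based Brownian dynamics of membrane
    molecules in a compartmentalized plasma membrane. The actin membrane
    skeleton is represented as a periodic Voronoi fence mesh with a
    prescribed characteristic length, and the restriction it imposes on
    lateral diffusion is modelled in three interchangeable ways:
    probabilistic (hop) fences, triangular potential fences, and explicit
    immobile picket particles. The overdamped Langevin propagator supports
    pairwise repulsion, global drift, periodic or repulsive boundaries and
    voxel neighbour indexing. Observables include the ensemble mean squared
    displacement, time-resolved effective diffusion coefficients, radial
    distribution functions and compartment occupancy profiles. A
    finite-difference solver for one-dimensional diffusion across equally
    spaced semi-permeable barriers, with a least-squares permeability fit,
    serves as a validation oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
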