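Package: cortexfold
Title: Reversible Cortical-Folding Simulation and Geometry-Driven Fiber Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quasi-static simulation of cortical unfolding and refolding on
    two-tissue tetrahedral meshes using extended position-based dynamics
    (XPBD) with stable neo-Hookean tetrahedral constraints, surface-area
    contraction, and smoothing constraints. Provides a barycentric volumetric
    deformation map between folded and unfolded configurations, synthesis and
    advection of radial fibers and randomized Bezier bundles, voxel strain
    maps, and voxel-wise absolute-cosine-similarity evaluation of fiber
    orientation fields, together with synthetic folded geometries (sinusoidal
    slabs, unit cubes, wavy spheres) so the whole pipeline is testable
    without neuroimaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
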