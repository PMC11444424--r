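Package: curvdiff
Title: Geodesic Diffusion Analysis on Static Curved Membrane Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes spatially resolved geodesic mean-square-displacement
    (gMSD) and diffusion-coefficient maps for particles diffusing along static
    curved surfaces, such as lipids on buckled or budded bilayer leaflets.
    Triangulated leaflet surfaces are built from scattered particle positions
    by periodic Gaussian-kernel height-field gridding, characterized by
    discrete mean (cotangent Laplace-Beltrami) and Gaussian (angle-defect)
    curvature fields, and equipped with an exact polyhedral geodesic engine
    (continuous-Dijkstra window propagation over unfolded triangles) that
    returns all single-source distances without path reconstruction.
    Trajectories are snapped to mesh vertices, displacements are stored as
    sorted integer triplets so that one geodesic call per distinct source
    vertex evaluates a whole block, and the resulting per-vertex gMSD fields
    are converted to diffusion maps, curvature-class statistics with Welch
    tests, spatial profiles, and projected-versus-geodesic comparisons.
    A surface-constrained Brownian simulator on analytic reference surfaces
    (plane, sphere, cylinder, sinusoidal wave, Gaussian bud) provides ground
    truth with known diffusion coefficients and closed-form curvatures and
    geodesics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    parallel
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
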