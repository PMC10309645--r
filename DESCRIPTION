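Package: nasols
Title: Neighbor-Based Adaptive Sparsity Orthogonal Least Squares for
    Fluorescence Molecular Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Sparse reconstruction of fluorescent yield distributions in
    fluorescence molecular tomography (FMT). Provides a finite-element
    forward model for the coupled continuous-wave diffusion equations on
    tetrahedral meshes, a family of greedy L0 solvers for the resulting
    underdetermined linear system (NASOLS, adaptive-sparsity OLS,
    fixed-sparsity OLS, OMP, gOMP, CoSaMP), synthetic phantom experiment
    simulation with projection layouts and measurement noise, and the
    standard evaluation metrics (location error, NRMSE, contrast-to-noise
    ratio) including multi-target separation analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
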