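# nasols

Sparse reconstruction for fluorescence molecular tomography (FMT) in R.

FMT images a fluorescent probe inside strongly scattering tissue from light
measured on the surface. The discretized problem, `Phi_m = A X`, is severely
underdetermined: the nodal fluorescent yield `X` (mm^-1) has thousands of
unknowns, the surface measurements a few hundred rows. For small, bright
inclusions (early tumors) the natural prior is sparsity, which leads to the
L0-regularized program

```
min ||X||_0   subject to   ||A X - Phi_m||_2^2 < eps .
```

The package is built for researchers developing or benchmarking FMT
reconstruction: it implements the whole desk-scale loop — finite-element
diffusion forward model, greedy L0 solvers, synthetic phantom experiments,
and the standard evaluation metrics.

## What's inside

* **NASOLS** — neighbor-based adaptive sparsity orthogonal least squares,
  the package's core solver. Classical OLS scores every unselected column
  `a_j` by `||q_j||` with `q_j = (a_j' r / a_j' t_j) t_j` (`t_j` deflated
  against the accepted orthogonal basis) and needs the sparsity supplied in
  advance. NASOLS removes that requirement with an adaptive schedule
  (`K_i = K_{i-1} + ceil(K0/(i+1)^2)`, `L_i = L_{i-1} - ceil(L0/(i+1)^2)`,
  floored at 1) and restricts candidates to tetrahedral-edge neighbors
  `N(S_i)` of the current support, exploiting the spatial compactness of
  real fluorescent targets. This is what separates nearby double targets
  that unrestricted greedy pursuits merge into one blob.
* **Baselines** — ASOLS (no neighbor restriction), fixed-sparsity OLS, OMP,
  gOMP, CoSaMP, plus `restricted_lsq()` and an exhaustive-search oracle in
  the tests.
* **Forward model** — P1 FEM for the coupled continuous-wave diffusion
  equations (`D = 1/(3(mua + musp))`, Robin boundary condition) on
  tetrahedral meshes; Born coupling into the system matrix; optional
  normalized Born ratio.
* **Phantom simulator** — structured cube meshes with a fixed 6-tet split,
  spherical/cylindrical yield targets, rotational projection layouts with
  field-of-view detectors, seeded relative Gaussian noise, and
  forward/inverse mesh separation to avoid the inverse crime.
* **Metrics** — location error (LE), NRMSE, contrast-to-noise ratio (CNR),
  and connected-component analysis that decides whether multiple targets
  are resolved.
* **I/O and CLI** — TetGen-style `.node`/`.ele` and legacy VTK meshes,
  Matrix Market system matrices, CSV solutions/reports, and a thin command
  line (`inst/scripts/fmtrecon.R`) with `mesh`, `simulate`, `reconstruct`,
  `evaluate`, and `benchmark` subcommands.

## Worked example: resolving two 1 mm targets 4 mm apart

Two spheres (radius 1 mm, yield 0.05 mm^-1, edge-to-edge distance 4 mm) in
a 25 mm cube, 8 projections, noiseless; measurements are simulated on a
2x-finer mesh than the inversion uses:

```r
library(nasols)

targets <- list(target_spec(c(9.5, 12.5, 12.5),  1, 0.05),
                target_spec(c(15.5, 12.5, 12.5), 1, 0.05))
cfg <- experiment_config(spacing_mm = 25/16, targets = targets,
                         solvers = c("nasols", "ols"))
res <- run_experiment(cfg)
print(res$reports$nasols)
print(res$reports$ols)
```

```
fmt_report: 3 component(s), targets resolved
  target 1 at (9.50, 12.50, 12.50): rec (10.94, 12.70, 12.50), LE 1.45 mm
  target 2 at (15.50, 12.50, 12.50): rec (14.06, 12.60, 12.76), LE 1.46 mm
  NRMSE 0.06283, CNR -0.005763
fmt_report: 3 component(s), targets resolved
  target 1 at (9.50, 12.50, 12.50): rec (7.81, 12.50, 12.50), LE 1.69 mm
  target 2 at (15.50, 12.50, 12.50): rec (17.19, 12.50, 12.50), LE 1.69 mm
  NRMSE 0.02892, CNR -0.0163
```

Each report line gives the true target center, the energy-weighted centroid
of the matched reconstructed cluster, and their distance (the location
error). Both solvers separate the targets noiselessly — both centroids land
within one mesh node (1.5 mm here) of the truth. The difference appears
under measurement noise: across ten 5%-noise repeats NASOLS keeps resolving
both targets within 2 mm while fixed-sparsity OLS loses one in the majority
of repeats (`scripts/acceptance.R` reports this as
`eed4_ols_fewer_resolved_pct`). The negative CNR values are a reminder that
greedy point reconstructions concentrate energy on single nodes adjacent to
the 1--2 nodes inside the true spheres; CNR becomes informative for
extended reconstructions rather than near-point ones.

The solver can equally be called directly on any system:

```r
sol <- nasols(A, y, graph = edge_adjacency(mesh),
              config = solver_config(K0 = 6, L0 = 10, eps = 1e-8,
                                     eps_rel = TRUE))
sol$support          # selected mesh nodes, selection order
sol$history          # per-iteration K_i, L_i, ||r_i||
```

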