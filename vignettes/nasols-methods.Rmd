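---
title: "Sparse reconstruction for fluorescence molecular tomography: models, algorithms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse reconstruction for fluorescence molecular tomography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Fluorescence molecular tomography (FMT) reconstructs the 3-D distribution of
a fluorescent probe inside tissue from light measured on the surface. Tissue
scatters near-infrared light strongly, and far fewer surface measurements are
available than there are unknown interior values, so the inverse problem is
severely ill-posed. For early tumor imaging the unknown -- the nodal
*fluorescent yield* $X$ (mm$^{-1}$), the product of fluorophore absorption
and quantum efficiency -- is spatially sparse: a small bright inclusion in a
dark background. This package poses the reconstruction as L0-regularized
recovery,

$$\min_X \|X\|_0 \quad \text{s.t.} \quad \|A X - \Phi_m\|_2^2 < \varepsilon,$$

and solves it with greedy pursuit. Its core contribution is NASOLS
(neighbor-based adaptive sparsity orthogonal least squares): an OLS-type
pursuit that (i) does not need the sparsity level supplied in advance and
(ii) grows its support along the tetrahedral-mesh edges of the finite-element
discretization, exploiting the fact that a compact tumor occupies a connected
patch of mesh nodes.

## Forward model

Light propagation is modelled by the continuous-wave diffusion approximation
to the radiative transfer equation, valid in highly scattering tissue. Two
coupled diffusion equations describe the excitation and emission fields; each
is discretized with P1 (linear) finite elements on a tetrahedral mesh:

$$-\nabla\cdot(D\nabla\Phi) + \mu_a \Phi = q,
\qquad D = \frac{1}{3(\mu_a + \mu_s')},$$

with the Robin boundary condition $\Phi + 2 A_n D\, \partial\Phi/\partial n
= 0$. The Robin coefficient $A_n$ is computed from the refractive-index
mismatch by the standard effective-reflection polynomial and equals 1 for a
matched boundary. Assembly uses exact element integrals (consistent mass
matrix); the resulting sparse system is symmetric positive definite and is
factored once per wavelength with a sparse Cholesky decomposition.

Sources model collimated surface illumination as isotropic point sources one
transport mean free path ($1/\mu_s'$) beneath the surface, barycentrically
distributed over the enclosing element. Detectors are boundary nodes within a
configurable angular field of view (default 120 degrees) opposite each
source. Born (linear) coupling of the two solves gives the system matrix:
row $(s,d)$, column $j$ is $G_m(j,d)\,\Phi_x^{(s)}(j)\,V_j$, with $G_m$ the
emission-wavelength Green's factor obtained by one adjoint solve per
detector, $\Phi_x^{(s)}$ the excitation fluence of source $s$, and $V_j$ the
lumped nodal volume. Born coupling keeps the measurements exactly linear in
the yield, at the cost of ignoring re-absorption of emitted light by the
fluorophore -- the standard approximation for the low probe concentrations
of small-animal imaging.

Accuracy: on a homogeneous 25 mm cube with $\mu_a = 0.01$, $\mu_s' = 1.0$
mm$^{-1}$, the FEM fluence of a centered point source agrees with the
infinite-medium Green's function $e^{-\mu_{\rm eff} r}/(4\pi D r)$ to within
20% at radii 4--8 mm already at 2.5 mm node spacing, and the error decreases
under refinement; the residual discrepancy is dominated by the truncated
boundary, not the discretization.

## The NASOLS algorithm

All solvers operate on the columns $a_j$ of $A$. Each unselected column keeps
a deflated copy $t_j$, orthogonal to the accepted basis $\{u_l\}$. The OLS
score of a candidate is $\|q_j\|_2$ with
$q_j = (a_j^\top r / a_j^\top t_j)\, t_j$; accepting $j$ sets
$u \leftarrow q_j$, $r \leftarrow r - u$, and projects every deflated column
off $u$. This guarantees a monotonically non-increasing residual and an
exactly orthogonal basis, both of which are enforced by property tests.

NASOLS wraps this rule in two devices:

* **Adaptive sparsity schedule.** From initial values $(K_0, L_0)$, iteration
  $i$ updates $K_i = K_{i-1} + \lceil K_0/(i+1)^2\rceil$ and
  $L_i = L_{i-1} - \lceil L_0/(i+1)^2\rceil$ (floored at 1). $K_i$ is the
  number of leading selections kept in the final estimate, $L_i$ the number
  of columns added this iteration: large steps early to approach the true
  sparsity quickly, unit steps late. With the defaults $K_0=6$, $L_0=10$
  the sequences begin $K: 6, 8, 9, 10, \dots$ and $L: 10, 7, 5, 4, \dots$.
* **Neighbor candidate restriction.** After the initial batch, candidates are
  restricted to $E_i = N(S_i)$: the nodes sharing a tetrahedral edge with the
  current support, excluding the support itself (re-selecting an exhausted
  column would waste a slot). This keeps the support spatially coherent and
  is what separates adjacent targets that unrestricted pursuits merge.

The final estimate is restricted least squares on the first $K_i$ selected
columns, zeros elsewhere -- the universal convention for OLS/OMP-family
solvers. The comparison baselines (ASOLS without the neighbor restriction,
fixed-sparsity OLS, OMP, gOMP, CoSaMP) follow their standard published
forms, and the suite cross-checks `ols_fixed` against an exhaustive
best-support search on small instances.

### Batch selection semantics

Within one iteration, $L_i$ columns can be chosen either from a single
scoring pass (taking the $L_i$ largest scores) or by re-scoring after every
individual selection. The package defaults to the single pass. The reasons:
with re-scoring, the initial batch is mathematically identical to plain
sequential OLS, so NASOLS inherits OLS's single-blob behavior on nearby
double targets and the neighbor expansion has nothing distinctive to seed
from; the single pass keeps several correlated columns near a compact target
in the batch, which is precisely the local structure the neighbor strategy
exploits. On the double-target benchmark below, the single-pass variant
separates both targets in every noisy repeat while sequential OLS does not.
Both variants maintain the orthogonal basis exactly, because the accepted
projection $q_j$ is recomputed from the current residual and deflated column
at update time; re-scoring remains available via `solver_config(rescore =
TRUE)`.

### Halting and numerical safeguards

* $\varepsilon$ (default $10^{-8}$) halts on the residual norm. The absolute
  form is scale-fragile -- solving $(cA, cy)$ needs $c\varepsilon$ -- so the
  simulation drivers use the relative mode $\|r\|/\|y\| < \varepsilon$
  (`eps_rel = TRUE`); solvers are otherwise scale-equivariant, which a
  property test documents.
* With noisy or model-mismatched data the threshold is never reached, and
  the only remaining stop would be the iteration cap, by which time the
  support has grown far past the true sparsity and the restricted
  least-squares system is nearly singular. The adaptive solvers therefore
  also halt when an outer iteration improves the residual by less than
  `stall_tol` (default 1%), the conventional stagnation rule for pursuits
  with unknown sparsity. Setting `stall_tol = 0` disables it.
* Candidates whose deflated direction is numerically exhausted
  ($|a_j^\top t_j| < 10^{-12}\|a_j\|\|t_j\|$) are excluded for the iteration;
  ties in the argmax break to the lowest column index for cross-platform
  determinism.
* Restricted least squares is computed by SVD with a relative rank tolerance
  of $10^{-8}$: greedy supports on fine meshes routinely contain
  near-duplicate columns (observed condition numbers $\sim 10^9$), and
  amplifying those directions only fits noise. Truncated directions trigger
  a minimum-norm solution with a warning.
* If the halting condition was met, the reported support (first $K_i$
  selections) must also meet it; when truncation would lose a late-selected
  essential column, the support is extended along the selection order until
  the fit again attains the achieved residual. Non-converged runs keep the
  plain first-$K_i$ truncation.
* $K_i$ and the total number of selections are capped at
  $\min(\text{rows}, \text{columns})$; the outer loop at `max_iter`
  (default 50).

## Synthetic experiments

`experiment_config()` / `run_experiment()` reproduce the desk-scale protocol
the solvers are evaluated on:

* a 25 mm cube phantom meshed as a structured grid with a fixed six-tet
  (Kuhn) split per cell -- deterministic, so the adjacency graph is
  bit-identical across runs;
* spherical targets of radius 1 mm and yield 0.05 mm$^{-1}$ (cylindrical
  targets, e.g. fluorophore-filled drilled holes, are also supported);
* $n$ rotational projections: point sources equally spaced in angle in a
  transverse plane, each with detectors in a 120-degree field of view on the
  opposite side, subsampled to at most `max_detectors` (default 64) per
  projection -- a desk-scale stand-in for a CCD view;
* relative Gaussian measurement noise: "x% noise" multiplies each
  measurement by $(1 + x\% \cdot g_i)$ with $g_i$ i.i.d. standard normal,
  the common convention in this literature; negatives clamp to zero. An
  additive model is available. All noise is seeded and reproducible.

Optical properties default to $\mu_a = 0.02$, $\mu_s' = 1.0$ mm$^{-1}$,
$n = 1.37$ at both wavelengths -- generic soft-tissue values in the
near-infrared; they are configuration, not measurements, and heterogeneous
region-wise properties are supported.

**Avoiding the inverse crime.** Measurements are simulated on a mesh refined
by a factor of 2 relative to the inverse mesh. The two discretizations
disagree by up to $\pm 30\%$ per raw measurement -- structured model error
far larger than typical measurement noise. Real acquisition systems face the
same issue and feed the solver the *normalized Born ratio* (emission
divided by excitation at the same source-detector pair), which cancels the
error the two Green's factors share; measured on the cube, normalization
shrinks the inter-mesh discrepancy to about $\pm 12\%$. The simulation
driver therefore defaults to `normalization = "born"`; raw intensities
(`"none"`) remain the `build_system_matrix()` default. Detectors where the
excitation field is numerically dark (below $10^{-6}$ of the source's
brightest detector on either mesh) cannot normalize anything and are dropped
from both matrices.

What the generator does *not* emulate: organ-level heterogeneity of a real
animal, free-space CCD optics and calibration, autofluorescence, and
unstructured anatomical meshes. Passing the synthetic benchmarks therefore
demonstrates correctness of the algorithms and of the discretized physics,
not end-to-end performance on a physical system.

## Evaluation metrics

The published formulas behind the three standard indicators are not printed
in this literature's papers; the package implements the conventional forms
and isolates each so alternates can be swapped:

* **LE** (mm): Euclidean distance between the energy-weighted centroid of a
  reconstructed cluster and the true target center. Clusters are connected
  components (tetrahedral-edge connectivity) of the nodes above 10% of the
  image maximum (`support_frac`, configurable). The reconstructed targets
  are identified *blindly* as the highest-energy clusters (one per true
  target) and then matched to the true centers by greedy nearest-centroid
  matching without replacement; identifying clusters by proximity to the
  truth instead would let a negligible artifact near a target mask a
  displaced reconstruction. An unmatched target reports `NA` -- the
  reconstruction collapsed onto fewer spots than there are targets.
* **NRMSE**: node-wise RMSE divided by the dynamic range of the true image;
  zero iff exact, invariant under joint rescaling.
* **CNR**: $(\mu_{\rm ROI} - \mu_{\rm BCK}) / \sqrt{w_{\rm ROI}
  \sigma^2_{\rm ROI} + w_{\rm BCK}\sigma^2_{\rm BCK}}$ with node-count
  fractions as weights and population variances; the ROI is the true target
  node set. Invariant under positive rescaling of the reconstruction.

## Problem sizes and known limitations

The shipped tests and the acceptance script run at desk scale, chosen so the
whole suite completes on one CPU: inverse meshes of 1331 nodes (2.5 mm
spacing) for single-target studies and 4913 nodes (25/16 mm) for
double-target resolution studies, forward meshes refined 2x (up to 35,937
nodes), 8 projections, and at most 64 detectors per projection
(~512 measurement rows). Exact-recovery and oracle studies use random
64 x 200 and 20 x 30 unit-column Gaussian systems.

Two desk-scale effects are worth knowing about:

* The location-error floor is set by the inverse-mesh spacing and the
  residual inter-mesh model bias (about one lattice node), not by
  measurement noise: i.i.d. relative noise averages out across the ~512
  measurements entering each OLS score, so LE-versus-noise curves are nearly
  flat here, unlike on anatomical meshes where model error and noise
  interact more strongly. The noise-robustness test asserts only that LE
  does not *improve* with noise beyond statistical uncertainty.
* Random test meshes are jittered structured grids rather than Delaunay
  tetrahedralizations; every property exercised (adjacency, neighbor
  expansion, components) depends only on mesh combinatorics, not on the
  Delaunay criterion.

## Defaults at a glance

| Parameter | Default | Meaning |
|---|---|---|
| `K0` | 6 | initial sparsity (final-support seed) |
| `L0` | 10 | initial selection width |
| `eps` | 1e-8 | residual halting threshold (relative in drivers) |
| `stall_tol` | 0.01 | minimum relative residual improvement per iteration |
| `max_iter` | 50 | outer iteration cap |
| ASOLS/OLS/CoSaMP/gOMP sparsity | 4 / 10 / 8 / 6 | comparison settings |
| `fov_deg` | 120 | detector field of view |
| `max_detectors` | 64 | detectors kept per projection |
| `refine` | 2 | forward/inverse mesh spacing ratio |
| `support_frac` | 0.1 | cluster threshold for evaluation |

`K0 = 6`, `L0 = 10` follow the published parameter study for this algorithm
family; `sweep_schedule()` reruns that study at reduced scale on any
configured experiment.
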