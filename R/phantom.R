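# Synthetic phantom experiments at desk scale: spherical/cylindrical yield
# targets, rotational projection layouts, relative Gaussian measurement
# noise, and the end-to-end driver that simulates measurements on a refined
# forward mesh and reconstructs on a coarser inverse mesh (avoiding the
# inverse crime).

#' Specify a fluorescent target
#'
#' @param center length-3 center (mm).
#' @param radius target radius (mm), > 0.
#' @param yield_value fluorescent yield inside the target (mm^-1), > 0.
#' @param shape `"sphere"` or `"cylinder"` (axis-aligned, e.g. a drilled hole
#'   filled with fluorophore solution).
#' @param height cylinder height (mm); required for cylinders.
#' @param axis cylinder axis (default z).
#' @return object of class `target_spec`.
#' @examples
#' target_spec(c(18, 12, 16.4), radius = 1, yield_value = 0.05)
#' @export
target_spec <- function(center, radius, yield_value = 0.05,
                        shape = c("sphere", "cylinder"), height = NULL,
                        axis = c(0, 0, 1)) {
  shape <- match.arg(shape)
  center <- as.numeric(center)
  if (length(center) != 3) stop("`center` must be a length-3 point (mm)")
  if (!is.numeric(radius) || radius <= 0) stop("`radius` must be > 0")
  if (!is.numeric(yield_value) || yield_value <= 0)
    stop("`yield_value` must be > 0")
  if (shape == "cylinder" && (is.null(height) || height <= 0))
    stop("cylinder targets need a positive `height`")
  axis <- as.numeric(axis)
  axis <- axis / sqrt(sum(axis^2))
  structure(list(center = center, radius = radius,
                 yield_value = yield_value, shape = shape, height = height,
                 axis = axis),
            class = "target_spec")
}

.nodes_in_target <- function(nodes, t) {
  rel <- sweep(nodes, 2, t$center)
  if (t$shape == "sphere") {
    rowSums(rel^2) <= t$radius^2
  } else {
    ax <- rel %*% t$axis
    rad2 <- rowSums(rel^2) - ax[, 1]^2
    rad2 <= t$radius^2 & abs(ax[, 1]) <= t$height / 2
  }
}

#' Build a nodal yield phantom
#'
#' Nodal field equal to the target's `yield_value` at nodes inside any
#' target, zero elsewhere; overlapping targets take the maximum.
#'
#' @param mesh a `tet_mesh`.
#' @param targets list of [target_spec()]s (possibly empty).
#' @param warn warn when a target encloses no node (target smaller than the
#'   mesh resolution).
#' @return numeric yield vector of length `n_nodes(mesh)`.
#' @export
make_yield_phantom <- function(mesh, targets, warn = TRUE) {
  x <- numeric(nrow(mesh$nodes))
  for (t in targets) {
    if (!inherits(t, "target_spec")) stop("`targets` must be target_spec()s")
    inside <- .nodes_in_target(mesh$nodes, t)
    if (warn && !any(inside))
      warning("target at (", paste(signif(t$center, 4), collapse = ", "),
              ") encloses no mesh node; it is below the mesh resolution")
    x <- pmax(x, t$yield_value * inside)
  }
  x
}

# First-hit of a ray with the boundary triangles (Moller-Trumbore, vectorized
# over faces); returns the exit point in direction `dir` from `origin`.
.ray_boundary_exit <- function(mesh, patch, origin, dir) {
  p1 <- mesh$nodes[patch$faces[, 1], , drop = FALSE]
  p2 <- mesh$nodes[patch$faces[, 2], , drop = FALSE]
  p3 <- mesh$nodes[patch$faces[, 3], , drop = FALSE]
  e1 <- p2 - p1
  e2 <- p3 - p1
  dmat <- matrix(dir, nrow(p1), 3, byrow = TRUE)
  pv <- .cross3(dmat, e2)
  det <- rowSums(e1 * pv)
  ok <- abs(det) > 1e-12
  tv <- -sweep(p1, 2, origin) # origin - p1
  u <- rowSums(tv * pv) / det
  qv <- .cross3(tv, e1)
  v <- rowSums(dmat * qv) / det
  tt <- rowSums(e2 * qv) / det
  hit <- ok & u >= -1e-9 & v >= -1e-9 & (u + v) <= 1 + 1e-9 & tt > 1e-9
  if (!any(hit)) stop("projection ray does not intersect the boundary")
  tbest <- max(tt[hit]) # exit point (farthest forward intersection)
  origin + tbest * dir
}

#' Equally spaced rotational projection layout
#'
#' `n` source anchors on the boundary at the axial plane `plane_coord`,
#' equally spaced in angle about `axis` (one anchor per rotational view of
#' the gantry/phantom). Anchors are obtained by casting rays from the
#' in-plane centroid outward and taking the boundary intersection, so the
#' layout is deterministic and exact in angle.
#'
#' @param mesh a `tet_mesh`.
#' @param patch its [boundary_patch()].
#' @param n number of projections, >= 1.
#' @param plane_coord axial coordinate of the source plane (mm); defaults to
#'   the mid-plane.
#' @param axis rotation axis (default z).
#' @param start_deg angle of the first source (degrees).
#' @return `n x 3` matrix of surface anchor points (mm).
#' @export
layout_projections <- function(mesh, patch, n, plane_coord = NULL,
                               axis = c(0, 0, 1), start_deg = 0) {
  n <- as.integer(n)
  if (n < 1L) stop("`n` must be >= 1")
  frame <- .axis_frame(axis)
  centroid <- colMeans(mesh$nodes)
  axcoord <- mesh$nodes %*% frame$axis
  if (is.null(plane_coord)) plane_coord <- mean(range(axcoord))
  if (plane_coord < min(axcoord) || plane_coord > max(axcoord))
    stop("`plane_coord` lies outside the mesh")
  origin <- centroid + (plane_coord - sum(centroid * frame$axis)) * frame$axis
  angles <- (start_deg * pi / 180) + 2 * pi * (seq_len(n) - 1) / n
  anchors <- t(vapply(angles, function(th) {
    dir <- cos(th) * frame$e1 + sin(th) * frame$e2
    .ray_boundary_exit(mesh, patch, origin, dir)
  }, numeric(3)))
  anchors
}

#' Simulate surface measurements with relative Gaussian noise
#'
#' `y = A x_true`, then `y_i <- y_i (1 + noise_level * g_i)` with `g_i` iid
#' standard normal ("X percent Gaussian noise" = standard deviation of X
#' percent of each measurement, the usual convention for FMT measurements);
#' negative values are clamped to zero. An additive model with fixed standard
#' deviation is available instead.
#'
#' @param A a `system_matrix` or plain matrix.
#' @param x_true nodal yield phantom aligned with the columns of `A`.
#' @param noise_level relative noise fraction in `[0, 1)`.
#' @param seed integer seed for reproducible noise (optional).
#' @param model `"relative"` (default) or `"additive"`.
#' @param sd_abs absolute noise standard deviation (additive model only).
#' @return numeric measurement vector.
#' @export
simulate_measurements <- function(A, x_true, noise_level = 0, seed = NULL,
                                  model = c("relative", "additive"),
                                  sd_abs = NULL) {
  model <- match.arg(model)
  if (inherits(A, "system_matrix")) A <- A$A
  if (noise_level < 0 || noise_level >= 1)
    stop("`noise_level` must lie in [0, 1)")
  y <- as.numeric(A %*% as.numeric(x_true))
  add_noise(y, noise_level, seed = seed, model = model, sd_abs = sd_abs)
}

#' Apply the measurement noise model to a noiseless vector
#'
#' @param y0 noiseless measurement vector.
#' @inheritParams simulate_measurements
#' @return noisy, nonnegative measurement vector.
#' @export
add_noise <- function(y0, noise_level, seed = NULL,
                      model = c("relative", "additive"), sd_abs = NULL) {
  model <- match.arg(model)
  if (noise_level == 0 && model == "relative") return(y0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  g <- stats::rnorm(length(y0))
  y <- if (model == "relative") y0 * (1 + noise_level * g)
       else y0 + (if (is.null(sd_abs)) noise_level * mean(abs(y0)) else
                    sd_abs) * g
  pmax(y, 0)
}

#' Configure a synthetic cube experiment
#'
#' Defaults reproduce the desk-scale protocol: a 25 mm cube, spherical
#' targets of radius 1 mm and yield 0.05 mm^-1, point sources one transport
#' mean free path beneath the surface at equally spaced angles in the
#' mid-plane, detectors on the opposite side within a 120 degree field of
#' view, measurements simulated on a mesh refined by a factor of 2 relative
#' to the inverse mesh, and solver parameters K0 = 6, L0 = 10, halting
#' threshold 1e-8 (relative mode, since simulated measurement units are
#' arbitrary), with comparison sparsities ASOLS 4, OLS 10, CoSaMP 8, gOMP 6.
#'
#' @param side_mm cube side (mm).
#' @param spacing_mm inverse-mesh grid spacing (mm).
#' @param refine forward-mesh refinement factor (>= 1; 1 commits the inverse
#'   crime and is allowed only for diagnostics).
#' @param targets list of [target_spec()]s.
#' @param n_projections number of rotational projections.
#' @param fov_deg detector field of view (degrees).
#' @param plane_coord source plane (mm); default mid-plane.
#' @param noise_level relative measurement noise fraction.
#' @param seed integer seed for the noise.
#' @param max_detectors detector nodes kept per projection.
#' @param props_x,props_m optical properties at the excitation and emission
#'   wavelengths.
#' @param solvers character vector among
#'   `c("nasols", "asols", "ols", "cosamp", "gomp")`.
#' @param K0,L0,eps,eps_rel,max_iter NASOLS/ASOLS parameters
#'   (see [solver_config()]).
#' @param sparsity named integer vector of comparison sparsities.
#' @param asols_K0 initial sparsity for ASOLS.
#' @param support_frac threshold for [evaluate_reconstruction()].
#' @param normalization `"born"` (default) or `"none"`; with the forward
#'   data generated on a finer mesh than the inverse mesh, the normalized
#'   Born ratio cancels the source/detector modelling error the two meshes
#'   share (see [build_system_matrix()]).
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(side_mm = 25, spacing_mm = 2.5, refine = 2,
                              targets = list(target_spec(c(15.6, 12.5, 12.5),
                                                         1, 0.05)),
                              n_projections = 8, fov_deg = 120,
                              plane_coord = NULL, noise_level = 0, seed = 1L,
                              max_detectors = 64,
                              props_x = optical_properties(0.02, 1.0, 1.37),
                              props_m = optical_properties(0.02, 1.0, 1.37),
                              solvers = c("nasols", "asols", "ols",
                                          "cosamp", "gomp"),
                              K0 = 6, L0 = 10, eps = 1e-8, eps_rel = TRUE,
                              max_iter = 50,
                              sparsity = c(ols = 10, cosamp = 8, gomp = 6),
                              asols_K0 = 4, support_frac = 0.1,
                              normalization = c("born", "none")) {
  normalization <- match.arg(normalization)
  if (n_projections < 1) stop("`n_projections` must be >= 1")
  if (noise_level < 0 || noise_level >= 1)
    stop("`noise_level` must lie in [0, 1)")
  if (refine < 1) stop("`refine` must be >= 1")
  solvers <- match.arg(solvers, c("nasols", "asols", "ols", "cosamp",
                                  "gomp"), several.ok = TRUE)
  structure(list(side_mm = side_mm, spacing_mm = spacing_mm, refine = refine,
                 targets = targets, n_projections = as.integer(n_projections),
                 fov_deg = fov_deg, plane_coord = plane_coord,
                 noise_level = noise_level, seed = as.integer(seed),
                 max_detectors = max_detectors, props_x = props_x,
                 props_m = props_m, solvers = solvers, K0 = K0, L0 = L0,
                 eps = eps, eps_rel = eps_rel, max_iter = max_iter,
                 sparsity = sparsity, asols_K0 = asols_K0,
                 support_frac = support_frac, normalization = normalization),
            class = "experiment_config")
}

#' Build the forward/inverse systems of a cube experiment
#'
#' Generates the inverse mesh and a `refine`-times finer forward mesh, lays
#' out the sources, selects field-of-view detectors on the inverse boundary
#' (mapped to nearest boundary nodes of the forward mesh so both matrices
#' share physical measurement sites), builds the inverse system matrix, and
#' simulates the noiseless measurements from the phantom on the forward
#' mesh. The forward matrix is discarded after use; only its dimensions are
#' kept.
#'
#' @param cfg an [experiment_config()].
#' @return list with the inverse `mesh`, `graph`, `A` (inverse system
#'   matrix), `row_index`, `y0` (noiseless measurements), `x_true` (phantom
#'   on the inverse mesh), `anchors`, `detectors`, and `fwd_dims`.
#' @export
build_experiment_system <- function(cfg) {
  mesh_inv <- generate_cube_mesh(cfg$side_mm, cfg$spacing_mm)
  mesh_fwd <- if (cfg$refine > 1)
    generate_cube_mesh(cfg$side_mm, cfg$spacing_mm / cfg$refine) else mesh_inv
  patch_inv <- boundary_patch(mesh_inv)
  patch_fwd <- if (cfg$refine > 1) boundary_patch(mesh_fwd) else patch_inv
  anchors <- layout_projections(mesh_inv, patch_inv, cfg$n_projections,
                                plane_coord = cfg$plane_coord)
  musp <- cfg$props_x$musp
  src_inv <- lapply(seq_len(nrow(anchors)), function(k)
    place_point_source(mesh_inv, patch_inv, anchors[k, ], musp))
  det_inv <- lapply(src_inv, function(s)
    select_detectors_fov(mesh_inv, patch_inv, s, cfg$fov_deg,
                         max_detectors = cfg$max_detectors))
  A_inv <- build_system_matrix(mesh_inv, cfg$props_x, cfg$props_m, src_inv,
                               det_inv, patch_inv,
                               normalize = cfg$normalization)
  det_inv <- A_inv$detectors # Born mode may have dropped dark detectors
  A <- A_inv$A
  row_index <- A_inv$row_index
  if (cfg$refine > 1) {
    src_fwd <- lapply(seq_len(nrow(anchors)), function(k)
      place_point_source(mesh_fwd, patch_fwd, anchors[k, ], musp))
    bn_fwd <- patch_fwd$boundary_nodes
    bpos <- mesh_fwd$nodes[bn_fwd, , drop = FALSE]
    det_fwd <- lapply(det_inv, function(d) {
      pos <- mesh_inv$nodes[as.integer(d), , drop = FALSE]
      vapply(seq_len(nrow(pos)), function(r)
        bn_fwd[which.min(colSums((t(bpos) - pos[r, ])^2))], integer(1))
    })
    A_fwd <- build_system_matrix(mesh_fwd, cfg$props_x, cfg$props_m, src_fwd,
                                 det_fwd, patch_fwd,
                                 normalize = cfg$normalization)
    # a (source, detector) pair dark on either mesh is dropped from both
    keep <- unlist(A_fwd$kept_mask)
    if (!all(keep)) {
      A <- A[keep, , drop = FALSE]
      row_index <- row_index[keep, , drop = FALSE]
      det_inv <- Map(function(d, k) d[k], det_inv, A_fwd$kept_mask)
    }
    x_fwd <- make_yield_phantom(mesh_fwd, cfg$targets)
    y0 <- as.numeric(A_fwd$A %*% x_fwd)
    fwd_dims <- dim(A_fwd$A)
    rm(A_fwd)
  } else {
    x_fwd <- make_yield_phantom(mesh_inv, cfg$targets)
    y0 <- as.numeric(A %*% x_fwd)
    fwd_dims <- dim(A)
  }
  list(config = cfg, mesh = mesh_inv, graph = edge_adjacency(mesh_inv),
       A = A, row_index = row_index, y0 = y0,
       x_true = make_yield_phantom(mesh_inv, cfg$targets, warn = FALSE),
       anchors = anchors, detectors = det_inv, fwd_dims = fwd_dims)
}

#' Run the configured solvers on a built experiment system
#'
#' @param sys a system from [build_experiment_system()].
#' @param noise_level,seed noise applied to `sys$y0` (default from the
#'   config).
#' @return list with `y`, named `solutions`, and named `reports`.
#' @export
run_solvers <- function(sys, noise_level = NULL, seed = NULL) {
  cfg <- sys$config
  if (is.null(noise_level)) noise_level <- cfg$noise_level
  if (is.null(seed)) seed <- cfg$seed
  y <- add_noise(sys$y0, noise_level, seed = seed)
  base_cfg <- solver_config(K0 = cfg$K0, L0 = cfg$L0, eps = cfg$eps,
                            eps_rel = cfg$eps_rel, max_iter = cfg$max_iter)
  asols_cfg <- solver_config(K0 = cfg$asols_K0, L0 = cfg$L0, eps = cfg$eps,
                             eps_rel = cfg$eps_rel, max_iter = cfg$max_iter)
  sols <- list()
  for (sv in cfg$solvers) {
    sols[[sv]] <- switch(sv,
      nasols = nasols(sys$A, y, sys$graph, base_cfg),
      asols = asols(sys$A, y, asols_cfg),
      ols = ols_fixed(sys$A, y, K = cfg$sparsity[["ols"]], eps = cfg$eps,
                      eps_rel = cfg$eps_rel),
      cosamp = cosamp(sys$A, y, K = cfg$sparsity[["cosamp"]], eps = cfg$eps,
                      eps_rel = cfg$eps_rel),
      gomp = gomp(sys$A, y, K = cfg$sparsity[["gomp"]], eps = cfg$eps,
                  eps_rel = cfg$eps_rel))
  }
  reports <- lapply(sols, function(s)
    evaluate_reconstruction(s$x_hat, sys$x_true, cfg$targets, sys$mesh,
                            sys$graph, support_frac = cfg$support_frac))
  list(y = y, solutions = sols, reports = reports)
}

#' Run a complete synthetic experiment
#'
#' Builds the forward/inverse systems, simulates noisy measurements, runs
#' every configured solver, and evaluates each reconstruction. Fully
#' reproducible from the config (including its seed).
#'
#' @param cfg an [experiment_config()].
#' @return list with `config`, `system` (dimensions), `y`, `solutions`,
#'   `reports`, and a `summary` data.frame (one row per solver and target).
#' @export
run_experiment <- function(cfg) {
  sys <- build_experiment_system(cfg)
  res <- run_solvers(sys)
  summary <- do.call(rbind, lapply(names(res$reports), function(nm)
    report_as_table(res$reports[[nm]], method = nm)))
  list(config = cfg,
       system = list(inverse_dims = dim(sys$A), forward_dims = sys$fwd_dims,
                     n_sources = nrow(sys$anchors)),
       y = res$y, x_true = sys$x_true,
       solutions = res$solutions, reports = res$reports, summary = summary)
}

#' Sweep measurement noise levels over repeated seeds
#'
#' Builds the experiment system once and re-runs the solvers at each noise
#' level for each seed.
#'
#' @param cfg an [experiment_config()].
#' @param noise_levels numeric vector of relative noise fractions.
#' @param seeds integer vector of noise seeds.
#' @return data.frame: one row per (noise level, seed, solver, target).
#' @export
sweep_noise <- function(cfg, noise_levels, seeds) {
  sys <- build_experiment_system(cfg)
  out <- list()
  for (nl in noise_levels) {
    for (sd in seeds) {
      res <- run_solvers(sys, noise_level = nl, seed = sd)
      for (nm in names(res$reports)) {
        tb <- report_as_table(res$reports[[nm]], method = nm)
        tb$noise_level <- nl
        tb$seed <- sd
        out[[length(out) + 1L]] <- tb
      }
    }
  }
  do.call(rbind, out)
}

#' Sweep the number of projections
#'
#' @param cfg an [experiment_config()].
#' @param projections integer vector of projection counts.
#' @return data.frame as in [sweep_noise()] with a `projections` column.
#' @export
sweep_projections <- function(cfg, projections = c(2, 4, 8, 16)) {
  out <- list()
  for (np in projections) {
    cfg_np <- cfg
    cfg_np$n_projections <- as.integer(np)
    res <- run_experiment(cfg_np)
    tb <- res$summary
    tb$projections <- np
    out[[length(out) + 1L]] <- tb
  }
  do.call(rbind, out)
}

#' Sweep the NASOLS schedule parameters K0 and L0
#'
#' Builds the system once and reconstructs with NASOLS for every (K0, L0)
#' pair; the desk-scale analog of the published parameter-grid study.
#'
#' @param cfg an [experiment_config()].
#' @param K0_values,L0_values grids of initial schedule parameters.
#' @return data.frame: one row per (K0, L0, target).
#' @export
sweep_schedule <- function(cfg, K0_values = seq(6, 30, by = 6),
                           L0_values = seq(5, 25, by = 5)) {
  sys <- build_experiment_system(cfg)
  y <- add_noise(sys$y0, cfg$noise_level, seed = cfg$seed)
  out <- list()
  for (K0 in K0_values) {
    for (L0 in L0_values) {
      sol <- nasols(sys$A, y, sys$graph,
                    solver_config(K0 = K0, L0 = L0, eps = cfg$eps,
                                  eps_rel = cfg$eps_rel,
                                  max_iter = cfg$max_iter))
      rep <- evaluate_reconstruction(sol$x_hat, sys$x_true, cfg$targets,
                                     sys$mesh, sys$graph,
                                     support_frac = cfg$support_frac)
      tb <- report_as_table(rep, method = "nasols")
      tb$K0 <- K0
      tb$L0 <- L0
      out[[length(out) + 1L]] <- tb
    }
  }
  do.call(rbind, out)
}
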