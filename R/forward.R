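# Continuous-wave diffusion forward model. P1 Galerkin assembly of
#   -div(D grad Phi) + mua Phi = q,   D = 1/(3 (mua + musp)),
# with the Robin boundary condition Phi + 2 A_n D dPhi/dn = 0, solved at the
# excitation and emission wavelengths. Born coupling of the two solves yields
# the linear system matrix mapping nodal fluorescent yield to surface
# measurements.

#' Optical properties of a tissue region
#'
#' One record per region label and wavelength band. `mua` is the absorption
#' coefficient, `musp` the reduced scattering coefficient (both mm^-1), and
#' `n_refr` the refractive index used in the Robin boundary coefficient.
#'
#' @param mua absorption coefficient (mm^-1), > 0.
#' @param musp reduced scattering coefficient (mm^-1), > 0.
#' @param n_refr refractive index, >= 1.
#' @return object of class `optical_properties`.
#' @examples
#' optical_properties(mua = 0.02, musp = 1.0, n_refr = 1.37)
#' @export
optical_properties <- function(mua, musp, n_refr = 1.37) {
  if (!is.numeric(mua) || mua <= 0) stop("`mua` must be > 0 (mm^-1)")
  if (!is.numeric(musp) || musp <= 0) stop("`musp` must be > 0 (mm^-1)")
  if (!is.numeric(n_refr) || n_refr < 1) stop("`n_refr` must be >= 1")
  structure(list(mua = mua, musp = musp, n_refr = n_refr),
            class = "optical_properties")
}

# Robin coefficient A_n from the refractive-index mismatch, via the standard
# effective-reflection polynomial; exactly 1 for a matched boundary.
.robin_An <- function(n_refr) {
  if (abs(n_refr - 1) < 1e-12) return(1)
  r_eff <- -1.440 / n_refr^2 + 0.710 / n_refr + 0.668 + 0.0636 * n_refr
  (1 + r_eff) / (1 - r_eff)
}

# Normalize props to a named list keyed by region label.
.props_by_region <- function(props, labels) {
  if (inherits(props, "optical_properties")) {
    out <- stats::setNames(rep(list(props), length(labels)),
                           as.character(labels))
    return(out)
  }
  if (!is.list(props) || is.null(names(props)))
    stop("`props` must be an `optical_properties` record or a named list ",
         "keyed by region label")
  missing <- setdiff(as.character(labels), names(props))
  if (length(missing))
    stop("no optical properties for region label(s): ",
         paste(missing, collapse = ", "))
  props
}

#' Assemble the FEM diffusion system
#'
#' Builds the symmetric positive-definite sparse matrix of the P1 Galerkin
#' discretization: element stiffness `D * V * (grad_i . grad_j)`, consistent
#' element mass `mua * V/20 * (1 + delta_ij)`, and the Robin boundary term
#' `area/12 * (1 + delta_ij) / (2 A_n)` on every boundary face.
#'
#' @param mesh a `tet_mesh`.
#' @param props an [optical_properties()] record (applied to all regions) or a
#'   named list of records keyed by region label.
#' @param patch optional precomputed [boundary_patch()].
#' @return object of class `diffusion_system`: list with the sparse matrix
#'   `K`, the `mesh` dimensions, per-element `D`, and a factorization cache.
#' @export
assemble_diffusion_system <- function(mesh, props, patch = NULL) {
  labels <- sort(unique(mesh$region))
  props <- .props_by_region(props, labels)
  n <- nrow(mesh$nodes)
  el <- mesh$elements
  geom <- .tet_geometry(mesh)
  reg <- as.character(mesh$region)
  mua_e <- vapply(props, function(p) p$mua, 0)[reg]
  musp_e <- vapply(props, function(p) p$musp, 0)[reg]
  D_e <- 1 / (3 * (mua_e + musp_e))
  grads <- list(geom$g1, geom$g2, geom$g3, geom$g4)
  V <- geom$vol

  m <- nrow(el)
  ii <- vector("list", 16)
  jj <- vector("list", 16)
  xx <- vector("list", 16)
  t <- 0L
  for (a in 1:4) {
    for (b in 1:4) {
      t <- t + 1L
      stiff <- D_e * V * rowSums(grads[[a]] * grads[[b]])
      mass <- mua_e * V / 20 * (1 + (a == b))
      ii[[t]] <- el[, a]
      jj[[t]] <- el[, b]
      xx[[t]] <- stiff + mass
    }
  }
  if (is.null(patch)) patch <- boundary_patch(mesh)
  An_e <- vapply(props, function(p) .robin_An(p$n_refr), 0)[reg]
  bc <- 1 / (2 * An_e[patch$element])
  bi <- vector("list", 9)
  bj <- vector("list", 9)
  bx <- vector("list", 9)
  t <- 0L
  for (a in 1:3) {
    for (b in 1:3) {
      t <- t + 1L
      bi[[t]] <- patch$faces[, a]
      bj[[t]] <- patch$faces[, b]
      bx[[t]] <- bc * patch$areas / 12 * (1 + (a == b))
    }
  }
  K <- Matrix::sparseMatrix(i = c(unlist(ii), unlist(bi)),
                            j = c(unlist(jj), unlist(bj)),
                            x = c(unlist(xx), unlist(bx)),
                            dims = c(n, n))
  K <- Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
  structure(list(K = K, n_nodes = n, D = D_e, patch = patch,
                 cache = new.env(parent = emptyenv())),
            class = "diffusion_system")
}

#' Solve a diffusion system for one or more load vectors
#'
#' The sparse Cholesky factorization is computed on first use and cached, so
#' repeated solves (one adjoint solve per detector) only cost triangular
#' substitutions.
#'
#' @param sys a `diffusion_system`.
#' @param b numeric vector, dense matrix, or sparse matrix of right-hand
#'   sides (columns).
#' @param clamp if `TRUE` (default), negligible negative fluence values from
#'   the P1 discretization are clamped to zero so that downstream system
#'   matrices are nonnegative.
#' @return numeric vector or matrix of nodal fluence values.
#' @export
solve_diffusion <- function(sys, b, clamp = TRUE) {
  if (is.null(sys$cache$chol))
    sys$cache$chol <- Matrix::Cholesky(sys$K, LDL = FALSE)
  vec <- is.null(dim(b))
  if (vec) b <- Matrix::Matrix(b, ncol = 1)
  phi <- as.matrix(Matrix::solve(sys$cache$chol, b, system = "A"))
  if (clamp) phi[phi < 0] <- 0
  if (vec) as.numeric(phi) else phi
}

#' Place an isotropic point source beneath the surface
#'
#' Collimated surface illumination is modelled as an isotropic point source
#' one transport mean free path (`1/musp`) beneath the boundary, along the
#' inward normal of the boundary face nearest the anchor. The unit load is
#' distributed to the vertices of the enclosing element by barycentric
#' weights.
#'
#' @param mesh a `tet_mesh`.
#' @param patch its [boundary_patch()].
#' @param anchor length-3 surface point (mm) near the boundary.
#' @param musp reduced scattering coefficient (mm^-1) of the region under the
#'   anchor; the source depth is `1/musp`.
#' @param amplitude source power (arbitrary units).
#' @return list with `load` (sparse length-n vector summing to `amplitude`)
#'   and `spec` (list: `surface_anchor`, `interior_position`, `amplitude`).
#' @export
place_point_source <- function(mesh, patch, anchor, musp, amplitude = 1) {
  anchor <- as.numeric(anchor)
  d2 <- rowSums(sweep(patch$centroids, 2, anchor)^2)
  f <- which.min(d2)
  inward <- -patch$normals[f, ]
  interior <- anchor + inward / musp
  loc <- tryCatch(locate_point(mesh, interior),
                  error = function(e) stop("interior source position (",
                                           paste(signif(interior, 6),
                                                 collapse = ", "),
                                           ") falls outside the mesh"))
  load <- Matrix::sparseVector(
    x = loc$weights * amplitude,
    i = as.integer(mesh$elements[loc$element, ]),
    length = nrow(mesh$nodes))
  list(load = load,
       spec = list(surface_anchor = anchor, interior_position = interior,
                   amplitude = amplitude))
}

.axis_frame <- function(axis) {
  axis <- axis / sqrt(sum(axis^2))
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  list(axis = axis, e1 = e1, e2 = e2)
}

.angle_about <- function(points, centroid, frame) {
  rel <- sweep(matrix(points, ncol = 3), 2, centroid)
  atan2(rel %*% frame$e2, rel %*% frame$e1)[, 1]
}

.wrap_angle <- function(a) atan2(sin(a), cos(a))

#' Select boundary detector nodes in a field of view opposite a source
#'
#' Detectors are the boundary nodes whose angular coordinate about `axis`
#' (measured in the plane orthogonal to `axis`, relative to the domain
#' centroid) lies within `+/- fov_deg/2` of the direction opposite the
#' source anchor -- the surface patch a camera facing the source would see.
#'
#' @param mesh a `tet_mesh`.
#' @param patch its [boundary_patch()].
#' @param source a source as returned by [place_point_source()] (its `spec`
#'   is used), or a length-3 anchor point.
#' @param fov_deg field of view in degrees, in (0, 360].
#' @param axis rotation axis (default z).
#' @param max_detectors optional cap; if the field of view contains more
#'   boundary nodes, an angularly even subsample of this size is returned.
#' @return integer vector of boundary node indices (class `detector_set`),
#'   ordered by angle.
#' @export
select_detectors_fov <- function(mesh, patch, source, fov_deg = 120,
                                 axis = c(0, 0, 1), max_detectors = Inf) {
  if (!is.numeric(fov_deg) || fov_deg <= 0 || fov_deg > 360)
    stop("`fov_deg` must lie in (0, 360]")
  anchor <- if (is.list(source)) source$spec$surface_anchor else
    as.numeric(source)
  frame <- .axis_frame(axis)
  centroid <- colMeans(mesh$nodes)
  bpos <- mesh$nodes[patch$boundary_nodes, , drop = FALSE]
  th_nodes <- .angle_about(bpos, centroid, frame)
  # nodes on the rotation axis have no defined angular coordinate
  rel <- sweep(bpos, 2, centroid)
  inplane <- sqrt(rowSums(rel^2) - (rel %*% frame$axis)[, 1]^2)
  th_src <- .angle_about(anchor, centroid, frame)
  dtheta <- abs(.wrap_angle(th_nodes - (th_src + pi)))
  sel <- dtheta <= (fov_deg / 2) * pi / 180 + 1e-12 &
    (inplane > 1e-9 | fov_deg >= 360)
  if (!any(sel))
    stop("empty detector set: no boundary node within the field of view")
  ids <- patch$boundary_nodes[sel]
  ang <- th_nodes[sel]
  ord <- order(ang, ids)
  ids <- ids[ord]
  if (is.finite(max_detectors) && length(ids) > max_detectors) {
    pick <- unique(round(seq(1, length(ids), length.out = max_detectors)))
    ids <- ids[pick]
  }
  structure(as.integer(ids), class = "detector_set")
}

#' Build the FMT system matrix
#'
#' Born coupling of the excitation and emission diffusion solves. For source
#' `s` the excitation fluence `Phi_x` is solved; for each detector node `d`
#' the emission-wavelength adjoint (point load at `d`) gives the Green's
#' factor `G_m(., d)`; the row for measurement pair `(s, d)` has entries
#' `A[(s,d), j] = G_m(j, d) * Phi_x(j) * V_j` with `V_j` the lumped nodal
#' volume. Rows are stacked source-major.
#'
#' @param mesh a `tet_mesh`.
#' @param props_x,props_m optical properties at the excitation and emission
#'   wavelengths (see [assemble_diffusion_system()]).
#' @param sources list of sources from [place_point_source()].
#' @param detectors list (one per source) of detector node index vectors.
#' @param patch optional precomputed [boundary_patch()].
#' @param normalize `"none"` (default; raw emission intensities) or
#'   `"born"`: divide each row and its measurement by the excitation
#'   measurement `Phi_x(d)` of the same (source, detector) pair -- the
#'   normalized Born ratio. The ratio form cancels most of the shared
#'   source/detector modelling error and is how acquired data are usually
#'   presented to the inverse problem.
#' @param min_excitation Born mode only: detectors whose excitation
#'   measurement falls below this fraction of the source's brightest
#'   detector are dropped (a dark detector cannot normalize anything; on
#'   coarse meshes the P1 fluence can even be nonpositive there). The kept
#'   detectors per source are reported in `kept_mask`.
#' @return object of class `system_matrix`: list with the dense matrix `A`
#'   (rows = stacked (source, detector) pairs, columns = mesh nodes),
#'   `row_index` (data.frame: `source`, `detector_node`, `row_scale`), and
#'   `n_nodes`. With `normalize = "born"`, `row_scale` holds the excitation
#'   measurements that divided each row.
#' @export
build_system_matrix <- function(mesh, props_x, props_m, sources, detectors,
                                patch = NULL,
                                normalize = c("none", "born"),
                                min_excitation = 1e-6) {
  normalize <- match.arg(normalize)
  stopifnot(length(sources) == length(detectors))
  if (is.null(patch)) patch <- boundary_patch(mesh)
  n <- nrow(mesh$nodes)
  bad <- setdiff(unique(unlist(detectors)), patch$boundary_nodes)
  if (length(bad))
    stop("detector node(s) not on the boundary: ",
         paste(utils::head(bad, 5), collapse = ", "))
  sys_x <- assemble_diffusion_system(mesh, props_x, patch)
  sys_m <- assemble_diffusion_system(mesh, props_m, patch)
  loads <- do.call(cbind, lapply(sources, function(s)
    Matrix::Matrix(s$load, ncol = 1)))
  phi_x_raw <- solve_diffusion(sys_x, loads, clamp = FALSE)
  phi_x <- pmax(phi_x_raw, 0)
  kept_mask <- lapply(detectors, function(d) rep(TRUE, length(d)))
  if (normalize == "born") {
    for (s in seq_along(sources)) {
      mx <- phi_x_raw[as.integer(detectors[[s]]), s]
      kept_mask[[s]] <- mx > min_excitation * max(mx, 0)
      if (!any(kept_mask[[s]]))
        stop("all detectors of source ", s, " are dark at the excitation ",
             "wavelength; cannot form the Born ratio")
    }
    detectors <- Map(function(d, k) as.integer(d)[k], detectors, kept_mask)
  }
  uniq_d <- sort(unique(as.integer(unlist(detectors))))
  rhs <- Matrix::sparseMatrix(i = uniq_d, j = seq_along(uniq_d), x = 1,
                              dims = c(n, length(uniq_d)))
  G <- solve_diffusion(sys_m, rhs)
  Vj <- nodal_volumes(mesh)
  rows_per <- lengths(detectors)
  A <- matrix(0, sum(rows_per), n)
  src_col <- integer(sum(rows_per))
  det_col <- integer(sum(rows_per))
  row_scale <- rep(1, sum(rows_per))
  at <- 0L
  for (s in seq_along(sources)) {
    w <- phi_x[, s] * Vj
    d_ids <- as.integer(detectors[[s]])
    cols <- match(d_ids, uniq_d)
    block <- t(G[, cols, drop = FALSE] * w)
    idx <- at + seq_len(rows_per[s])
    if (normalize == "born") {
      mx <- phi_x_raw[d_ids, s]
      block <- block / mx
      row_scale[idx] <- mx
    }
    A[idx, ] <- block
    src_col[idx] <- s
    det_col[idx] <- d_ids
    at <- at + rows_per[s]
  }
  structure(list(A = A,
                 row_index = data.frame(source = src_col,
                                        detector_node = det_col,
                                        row_scale = row_scale),
                 n_nodes = n, normalize = normalize,
                 detectors = detectors, kept_mask = kept_mask),
            class = "system_matrix")
}

#' @export
print.system_matrix <- function(x, ...) {
  cat(sprintf("system_matrix: %d measurement rows x %d nodes (%d sources)\n",
              nrow(x$A), ncol(x$A), length(unique(x$row_index$source))))
  invisible(x)
}

#' Infinite-medium diffusion Green's function
#'
#' `exp(-mu_eff r) / (4 pi D r)` with `mu_eff = sqrt(mua / D)`; the
#' closed-form reference against which the FEM solution is checked in a
#' homogeneous medium far from boundaries.
#'
#' @param r distance(s) from the source (mm).
#' @param props an [optical_properties()] record.
#' @return fluence values (same length as `r`).
#' @export
greens_infinite <- function(r, props) {
  D <- 1 / (3 * (props$mua + props$musp))
  mu_eff <- sqrt(props$mua / D)
  exp(-mu_eff * r) / (4 * pi * D * r)
}
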