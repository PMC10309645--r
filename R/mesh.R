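# Tetrahedral mesh primitives: construction and validation, structured cube
# meshing, boundary extraction, and the edge-adjacency neighbor operator that
# the support-growing solvers use.

.cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

.signed_volumes <- function(nodes, elements) {
  p1 <- nodes[elements[, 1], , drop = FALSE]
  a <- nodes[elements[, 2], , drop = FALSE] - p1
  b <- nodes[elements[, 3], , drop = FALSE] - p1
  d <- nodes[elements[, 4], , drop = FALSE] - p1
  rowSums(a * .cross3(b, d)) / 6
}

#' Construct a tetrahedral mesh
#'
#' A `tet_mesh` is the geometric substrate of the package: the unknown
#' fluorescent yield lives on its nodes, the finite-element forward model is
#' assembled on its elements, and the neighbor operator used by the
#' reconstruction solvers follows its edges.
#'
#' Elements are re-oriented to positive signed volume; degenerate
#' (zero-volume) tetrahedra and dangling node indices are rejected. Node and
#' element indexing is 1-based throughout the package; mesh file dialects
#' using 0-based indices are converted when read.
#'
#' @param nodes numeric `n x 3` matrix of node coordinates (mm).
#' @param elements integer `m x 4` matrix of node indices (1-based).
#' @param region optional integer vector of per-element region labels
#'   (organ/material id); defaults to a single region `1`.
#' @return An object of class `tet_mesh` with fields `nodes`, `elements`,
#'   `region`.
#' @examples
#' m <- tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
#'               matrix(1:4, 1))
#' n_nodes(m)
#' @export
tet_mesh <- function(nodes, elements, region = NULL) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  dimnames(nodes) <- NULL
  elements <- as.matrix(elements)
  storage.mode(elements) <- "integer"
  dimnames(elements) <- NULL
  if (ncol(nodes) != 3) stop("`nodes` must be an n x 3 coordinate matrix (mm)")
  if (ncol(elements) != 4) stop("`elements` must be an m x 4 connectivity matrix")
  if (anyNA(nodes) || anyNA(elements)) stop("mesh contains missing values")
  n <- nrow(nodes)
  if (n < 4) stop("a tetrahedral mesh needs at least 4 nodes")
  if (min(elements) < 1L || max(elements) > n)
    stop("element connectivity refers to node indices outside 1..", n)
  if (is.null(region)) {
    region <- rep(1L, nrow(elements))
  } else {
    region <- as.integer(region)
    if (length(region) != nrow(elements))
      stop("`region` must have one label per element")
  }
  sv <- .signed_volumes(nodes, elements)
  neg <- sv < 0
  if (any(neg)) {
    tmp <- elements[neg, 3L]
    elements[neg, 3L] <- elements[neg, 4L]
    elements[neg, 4L] <- tmp
    sv[neg] <- -sv[neg]
  }
  extent <- max(apply(nodes, 2, function(z) diff(range(z))))
  if (any(sv <= 1e-12 * max(extent^3, .Machine$double.xmin)))
    stop("mesh contains degenerate (zero-volume) tetrahedra")
  structure(list(nodes = nodes, elements = elements, region = region),
            class = "tet_mesh")
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("tet_mesh: %d nodes, %d tetrahedra, %d region(s)\n",
              nrow(x$nodes), nrow(x$elements), length(unique(x$region))))
  bb <- apply(x$nodes, 2, range)
  cat(sprintf("bounding box (mm): [%g, %g] x [%g, %g] x [%g, %g]\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

#' Mesh size accessors
#' @param mesh a `tet_mesh`.
#' @return integer count.
#' @export
n_nodes <- function(mesh) nrow(mesh$nodes)

#' @rdname n_nodes
#' @export
n_elements <- function(mesh) nrow(mesh$elements)

#' Element volumes (mm^3)
#' @param mesh a `tet_mesh`.
#' @return numeric vector of positive element volumes.
#' @export
element_volumes <- function(mesh) .signed_volumes(mesh$nodes, mesh$elements)

#' Lumped nodal volumes (mm^3)
#'
#' Each element distributes a quarter of its volume to each of its vertices.
#' Used as the quadrature weight of a nodal yield coefficient in the Born
#' coupling of the forward model.
#'
#' @param mesh a `tet_mesh`.
#' @return numeric vector of length `n_nodes(mesh)`.
#' @export
nodal_volumes <- function(mesh) {
  v <- element_volumes(mesh) / 4
  vn <- numeric(nrow(mesh$nodes))
  for (k in 1:4) {
    s <- rowsum(v, mesh$elements[, k])
    idx <- as.integer(rownames(s))
    vn[idx] <- vn[idx] + s[, 1]
  }
  vn
}

# Per-element geometry: positive volumes and the rows of the inverse Jacobian
# (== barycentric gradients). Shared by FEM assembly and point location.
.tet_geometry <- function(mesh) {
  nodes <- mesh$nodes
  el <- mesh$elements
  p1 <- nodes[el[, 1], , drop = FALSE]
  a <- nodes[el[, 2], , drop = FALSE] - p1
  b <- nodes[el[, 3], , drop = FALSE] - p1
  d <- nodes[el[, 4], , drop = FALSE] - p1
  det <- rowSums(a * .cross3(b, d)) # 6 * volume, positive by construction
  r1 <- .cross3(b, d) / det
  r2 <- .cross3(d, a) / det
  r3 <- .cross3(a, b) / det
  list(vol = det / 6, p1 = p1,
       g1 = -(r1 + r2 + r3), g2 = r1, g3 = r2, g4 = r3)
}

# Barycentric coordinates of one point in every element (n_elem x 4).
.barycentric_all <- function(geom, p) {
  v1 <- p[1] - geom$p1[, 1]
  v2 <- p[2] - geom$p1[, 2]
  v3 <- p[3] - geom$p1[, 3]
  l2 <- geom$g2[, 1] * v1 + geom$g2[, 2] * v2 + geom$g2[, 3] * v3
  l3 <- geom$g3[, 1] * v1 + geom$g3[, 2] * v2 + geom$g3[, 3] * v3
  l4 <- geom$g4[, 1] * v1 + geom$g4[, 2] * v2 + geom$g4[, 3] * v3
  cbind(1 - l2 - l3 - l4, l2, l3, l4)
}

#' Locate the element containing a point
#'
#' @param mesh a `tet_mesh`.
#' @param p numeric length-3 point (mm).
#' @param tol barycentric slack accepted outside an element face.
#' @return list with `element` (index) and `weights` (barycentric, length 4,
#'   clipped to be nonnegative and renormalized).
#' @export
locate_point <- function(mesh, p, tol = 1e-6) {
  geom <- .tet_geometry(mesh)
  lam <- .barycentric_all(geom, as.numeric(p))
  worst <- pmin(lam[, 1], lam[, 2], lam[, 3], lam[, 4])
  e <- which.max(worst)
  if (worst[e] < -tol)
    stop("point (", paste(signif(p, 6), collapse = ", "),
         ") lies outside the mesh")
  w <- pmax(lam[e, ], 0)
  list(element = e, weights = w / sum(w))
}

#' Generate a structured cube mesh
#'
#' Builds an axis-aligned cube `[0, side]^3` as a structured grid of
#' hexahedral cells, each split into six tetrahedra by the fixed Kuhn
#' decomposition (all tets share the cell's main diagonal). The split is the
#' same in every cell, so the mesh -- and therefore its edge-adjacency graph
#' -- is bit-identical across runs.
#'
#' @param side_mm cube side length (mm), > 0.
#' @param spacing_mm requested grid spacing (mm); the actual spacing is
#'   `side_mm / ceiling(side_mm / spacing_mm)`, never larger than requested.
#' @return a `tet_mesh` with `(k+1)^3` nodes where `k = ceiling(side/spacing)`.
#' @examples
#' m <- generate_cube_mesh(25, 12.5)
#' n_nodes(m) # 27
#' @export
generate_cube_mesh <- function(side_mm, spacing_mm) {
  if (!is.numeric(side_mm) || length(side_mm) != 1 || side_mm <= 0)
    stop("`side_mm` must be a positive length")
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 1 ||
      spacing_mm <= 0 || spacing_mm > side_mm)
    stop("`spacing_mm` must satisfy 0 < spacing_mm <= side_mm")
  nc <- max(1L, as.integer(ceiling(side_mm / spacing_mm - 1e-9)))
  .generate_grid_mesh(c(nc, nc, nc), c(side_mm, side_mm, side_mm))
}

# General structured grid (possibly anisotropic cell counts); cube meshing and
# the randomized test meshes are built on top of it.
.generate_grid_mesh <- function(ncell, extent) {
  nx <- ncell + 1L
  xs <- seq(0, extent[1], length.out = nx[1])
  ys <- seq(0, extent[2], length.out = nx[2])
  zs <- seq(0, extent[3], length.out = nx[3])
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs,
                                 KEEP.OUT.ATTRS = FALSE))
  dimnames(nodes) <- NULL
  idx <- function(i, j, k) 1L + i + nx[1] * (j + nx[2] * k) # 0-based i,j,k
  cells <- expand.grid(i = 0:(ncell[1] - 1L), j = 0:(ncell[2] - 1L),
                       k = 0:(ncell[3] - 1L), KEEP.OUT.ATTRS = FALSE)
  i <- cells$i; j <- cells$j; k <- cells$k
  c000 <- idx(i,      j,      k)
  c100 <- idx(i + 1L, j,      k)
  c010 <- idx(i,      j + 1L, k)
  c110 <- idx(i + 1L, j + 1L, k)
  c001 <- idx(i,      j,      k + 1L)
  c101 <- idx(i + 1L, j,      k + 1L)
  c011 <- idx(i,      j + 1L, k + 1L)
  c111 <- idx(i + 1L, j + 1L, k + 1L)
  # Kuhn split: one tet per monotone lattice path c000 -> c111.
  elements <- rbind(
    cbind(c000, c100, c110, c111),
    cbind(c000, c100, c101, c111),
    cbind(c000, c010, c110, c111),
    cbind(c000, c010, c011, c111),
    cbind(c000, c001, c101, c111),
    cbind(c000, c001, c011, c111))
  tet_mesh(nodes, elements)
}

#' Extract the boundary surface of a mesh
#'
#' Boundary faces are the triangles that belong to exactly one tetrahedron.
#' Outward unit normals are oriented away from the owning element's opposite
#' vertex (outward for any mesh whose boundary faces see their element on the
#' inside, in particular convex domains).
#'
#' @param mesh a `tet_mesh`.
#' @return an object of class `boundary_patch` with fields `faces` (`f x 3`
#'   node indices), `element` (owning element per face), `normals` (`f x 3`
#'   outward unit normals), `areas`, `centroids`, and `boundary_nodes`.
#' @export
boundary_patch <- function(mesh) {
  el <- mesh$elements
  n <- nrow(mesh$nodes)
  m <- nrow(el)
  faces <- rbind(el[, c(2, 3, 4)], el[, c(1, 3, 4)],
                 el[, c(1, 2, 4)], el[, c(1, 2, 3)])
  opp <- c(el[, 1], el[, 2], el[, 3], el[, 4])
  elem_id <- rep(seq_len(m), times = 4)
  a <- faces[, 1]; b <- faces[, 2]; d <- faces[, 3]
  lo <- pmin(a, b, d); hi <- pmax(a, b, d); mid <- a + b + d - lo - hi
  key <- (as.numeric(lo) - 1) * as.numeric(n)^2 + (mid - 1) * n + hi
  ord <- order(key)
  ks <- key[ord]
  same_next <- c(ks[-1] == ks[-length(ks)], FALSE)
  same_prev <- c(FALSE, same_next[-length(same_next)])
  bid <- ord[!(same_next | same_prev)]
  bfaces <- faces[bid, , drop = FALSE]
  belem <- elem_id[bid]
  bopp <- opp[bid]
  p1 <- mesh$nodes[bfaces[, 1], , drop = FALSE]
  p2 <- mesh$nodes[bfaces[, 2], , drop = FALSE]
  p3 <- mesh$nodes[bfaces[, 3], , drop = FALSE]
  nrm <- .cross3(p2 - p1, p3 - p1)
  cf <- (p1 + p2 + p3) / 3
  flip <- rowSums(nrm * (cf - mesh$nodes[bopp, , drop = FALSE])) < 0
  nrm[flip, ] <- -nrm[flip, ]
  len <- sqrt(rowSums(nrm^2))
  structure(list(faces = bfaces, element = belem, normals = nrm / len,
                 areas = len / 2, centroids = cf,
                 boundary_nodes = sort(unique(as.vector(bfaces)))),
            class = "boundary_patch")
}

#' @export
print.boundary_patch <- function(x, ...) {
  cat(sprintf("boundary_patch: %d faces, %d boundary nodes, area %.4g mm^2\n",
              nrow(x$faces), length(x$boundary_nodes), sum(x$areas)))
  invisible(x)
}

#' Edge adjacency of a tetrahedral mesh
#'
#' Two nodes are adjacent iff they appear together in at least one
#' tetrahedron (i.e. share a tetrahedral edge). The resulting graph is
#' symmetric and loop-free and carries the neighbor operator [neighbor_set()]
#' with which NASOLS grows its support set.
#'
#' @param mesh a `tet_mesh`.
#' @return an object of class `neighbor_graph`: list with `adjacency` (per-node
#'   sorted integer vectors) and `n_nodes`.
#' @export
edge_adjacency <- function(mesh) {
  el <- mesh$elements
  n <- nrow(mesh$nodes)
  pr <- rbind(el[, c(1, 2)], el[, c(1, 3)], el[, c(1, 4)],
              el[, c(2, 3)], el[, c(2, 4)], el[, c(3, 4)])
  i <- c(pr[, 1], pr[, 2])
  j <- c(pr[, 2], pr[, 1])
  keep <- !duplicated((as.numeric(i) - 1) * n + j)
  i <- i[keep]; j <- j[keep]
  ord <- order(i, j)
  adj <- split(j[ord], factor(i[ord], levels = seq_len(n)))
  structure(list(adjacency = unname(lapply(adj, as.integer)), n_nodes = n),
            class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  deg <- lengths(x$adjacency)
  cat(sprintf("neighbor_graph: %d nodes, %d edges, degree %d-%d\n",
              x$n_nodes, sum(deg) / 2, min(deg), max(deg)))
  invisible(x)
}

#' Neighbor operator N(.)
#'
#' Maps a support set to the union of all nodes sharing a tetrahedral edge
#' with any member, excluding the support itself. This is the candidate set
#' from which NASOLS selects new columns: keeping already-selected nodes in it
#' would waste selections on exhausted columns.
#'
#' @param graph a `neighbor_graph` from [edge_adjacency()].
#' @param support integer vector of node indices (may be empty).
#' @return sorted integer vector of neighboring node indices, disjoint from
#'   `support`.
#' @export
neighbor_set <- function(graph, support) {
  support <- as.integer(support)
  if (length(support) == 0L) return(integer(0))
  if (anyNA(support) || any(support < 1L | support > graph$n_nodes))
    stop("`support` contains invalid node indices")
  nb <- unique(unlist(graph$adjacency[support], use.names = FALSE))
  sort(setdiff(nb, support))
}

#' Connected components of a node subset
#'
#' Partitions `subset` into maximal groups connected through tetrahedral
#' edges. Used to decide whether a reconstruction resolves multiple targets
#' into distinct clusters.
#'
#' @param graph a `neighbor_graph`.
#' @param subset integer vector of node indices.
#' @return list of sorted integer vectors (one per component); empty list for
#'   an empty subset.
#' @export
connected_components <- function(graph, subset) {
  subset <- sort(unique(as.integer(subset)))
  if (length(subset) == 0L) return(list())
  if (anyNA(subset) || any(subset < 1L | subset > graph$n_nodes))
    stop("`subset` contains invalid node indices")
  pos <- integer(graph$n_nodes)
  pos[subset] <- seq_along(subset)
  ed <- vector("list", length(subset))
  for (s in seq_along(subset)) {
    tg <- graph$adjacency[[subset[s]]]
    tg <- tg[tg > subset[s]]
    tg <- tg[pos[tg] > 0L]
    if (length(tg)) ed[[s]] <- rbind(s, pos[tg])
  }
  edges <- do.call(cbind, ed)
  g <- igraph::make_empty_graph(n = length(subset), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, as.vector(edges))
  memb <- igraph::components(g)$membership
  unname(split(subset, memb))
}
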