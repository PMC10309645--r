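# Deterministic fixtures built in code.

# Two tets sharing the face {2,3,4}; node 5 is not edge-connected to node 1.
two_tet_mesh <- function() {
  tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1)),
           rbind(c(1, 2, 3, 4), c(2, 3, 4, 5)))
}

single_tet_mesh <- function() {
  tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
           matrix(1:4, 1))
}

# Random tetrahedralization: structured grid with jittered interior geometry
# (jitter kept small enough that the Kuhn tets stay positively oriented; the
# constructor validates and we back off if a draw degenerates).
jittered_grid_mesh <- function(ncell = c(4L, 4L, 4L), extent = ncell,
                               jitter = 0.2, seed = 1) {
  base <- nasols:::.generate_grid_mesh(as.integer(ncell), extent)
  h <- extent[1] / ncell[1]
  set.seed(seed)
  repeat {
    nodes <- base$nodes +
      matrix(stats::runif(length(base$nodes), -jitter * h, jitter * h),
             ncol = 3)
    m <- tryCatch(tet_mesh(nodes, base$elements), error = function(e) NULL)
    if (!is.null(m)) return(m)
    jitter <- jitter / 2
  }
}

# Unit-column Gaussian sensing matrix.
unit_gauss_A <- function(m, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(stats::rnorm(m * n), m)
  sweep(A, 2, sqrt(colSums(A^2)), "/")
}

# Edge-connected support of size k grown by random neighbor expansion.
connected_support <- function(graph, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sup <- sample(graph$n_nodes, 1)
  while (length(sup) < k) {
    nb <- neighbor_set(graph, sup)
    sup <- c(sup, nb[sample(length(nb), 1)])
  }
  sup
}

# Complete graph as a neighbor_graph (NASOLS on it must equal ASOLS).
complete_graph <- function(n) {
  structure(list(adjacency = lapply(seq_len(n), function(i)
    setdiff(seq_len(n), i)), n_nodes = n),
    class = "neighbor_graph")
}

rel_err <- function(x, x0) sqrt(sum((x - x0)^2)) / sqrt(sum(x0^2))

# Small, fast experiment config for pipeline tests.
tiny_experiment <- function(...) {
  experiment_config(side_mm = 25, spacing_mm = 5, refine = 2,
                    n_projections = 2, max_detectors = 12,
                    targets = list(target_spec(c(15, 10, 10), 2, 0.05)),
                    solvers = "nasols", ...)
}
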