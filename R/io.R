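# Mesh and matrix file plumbing. Supported mesh dialects: TetGen-style
# .node/.ele ASCII pairs (0- or 1-based, auto-detected) and legacy-ASCII VTK
# unstructured grids (tetrahedra only). System matrices persist as Matrix
# Market plus CSV sidecars so the artifacts stay text and interoperable.

#' Load a tetrahedral mesh from file
#'
#' @param path path to a `.node`/`.ele` pair (either member, or the common
#'   basename) or to a legacy-ASCII `.vtk` unstructured grid.
#' @param format `"auto"` (by extension), `"nodeele"`, or `"vtk"`.
#' @return a validated [tet_mesh()]. File node indexing (0- or 1-based) is
#'   auto-detected from the minimum index and normalized to the package's
#'   1-based convention.
#' @export
load_mesh <- function(path, format = c("auto", "nodeele", "vtk")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "vtk") "vtk" else "nodeele"
  }
  if (format == "vtk") .read_vtk_mesh(path) else .read_nodeele(path)
}

#' Save a tetrahedral mesh
#'
#' @param mesh a `tet_mesh`.
#' @param path output basename (for `"nodeele"`, `.node` and `.ele` are
#'   appended) or full `.vtk` path.
#' @param format `"nodeele"` or `"vtk"`.
#' @param point_data optional named list of per-node numeric vectors written
#'   as VTK point-data scalars (e.g. `list(yield = x)`).
#' @return the path(s) written, invisibly.
#' @export
save_mesh <- function(mesh, path, format = c("nodeele", "vtk"),
                      point_data = NULL) {
  format <- match.arg(format)
  if (format == "vtk") return(write_vtk(mesh, path, point_data))
  base <- sub("\\.(node|ele)$", "", path)
  nfile <- paste0(base, ".node")
  efile <- paste0(base, ".ele")
  n <- nrow(mesh$nodes)
  ncon <- file(nfile, "w")
  on.exit(close(ncon), add = TRUE)
  writeLines(sprintf("%d 3 0 0", n), ncon)
  writeLines(sprintf("%d %.17g %.17g %.17g", seq_len(n),
                     mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), ncon)
  econ <- file(efile, "w")
  on.exit(close(econ), add = TRUE)
  writeLines(sprintf("%d 4 1", nrow(mesh$elements)), econ)
  writeLines(sprintf("%d %d %d %d %d %d", seq_len(nrow(mesh$elements)),
                     mesh$elements[, 1], mesh$elements[, 2],
                     mesh$elements[, 3], mesh$elements[, 4], mesh$region),
             econ)
  invisible(c(nfile, efile))
}

.strip_comments <- function(lines) {
  lines <- sub("#.*$", "", lines)
  lines[nzchar(trimws(lines))]
}

.read_nodeele <- function(path) {
  base <- sub("\\.(node|ele)$", "", path)
  nfile <- paste0(base, ".node")
  efile <- paste0(base, ".ele")
  if (!file.exists(nfile) || !file.exists(efile))
    stop("expected a .node/.ele pair at basename '", base, "'")
  nl <- .strip_comments(readLines(nfile))
  hdr <- scan(text = nl[1], quiet = TRUE)
  nn <- as.integer(hdr[1])
  ntab <- matrix(scan(text = nl[-1], quiet = TRUE), nrow = nn, byrow = TRUE)
  node_ids <- as.integer(ntab[, 1])
  nodes <- ntab[, 2:4, drop = FALSE]
  el <- .strip_comments(readLines(efile))
  ehdr <- scan(text = el[1], quiet = TRUE)
  ne <- as.integer(ehdr[1])
  npe <- as.integer(ehdr[2])
  if (npe != 4)
    stop("unsupported element type: expected 4 nodes per element, got ", npe)
  etab <- matrix(scan(text = el[-1], quiet = TRUE), nrow = ne, byrow = TRUE)
  conn <- etab[, 2:5, drop = FALSE]
  region <- if (ncol(etab) >= 6) as.integer(etab[, 6]) else NULL
  offset <- 1L - min(node_ids) # 0-based files detected by minimum index
  remap <- integer(max(node_ids) + offset)
  remap[node_ids + offset] <- seq_len(nn)
  ci <- as.integer(conn) + offset
  if (anyNA(ci) || any(ci < 1L) || any(ci > length(remap)) ||
      any(remap[ci] == 0L))
    stop("element file references undefined node ids")
  conn <- matrix(remap[ci], ncol = 4)
  tet_mesh(nodes, conn, region)
}

#' Write a legacy-ASCII VTK unstructured grid
#'
#' @inheritParams save_mesh
#' @param path output `.vtk` path.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, point_data = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes)
  m <- nrow(mesh$elements)
  writeLines(c("# vtk DataFile Version 3.0",
               "tetrahedral mesh with nodal yield",
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.17g %.17g %.17g", mesh$nodes[, 1], mesh$nodes[, 2],
                     mesh$nodes[, 3]), con)
  writeLines(sprintf("CELLS %d %d", m, 5L * m), con)
  writeLines(sprintf("4 %d %d %d %d", mesh$elements[, 1] - 1L,
                     mesh$elements[, 2] - 1L, mesh$elements[, 3] - 1L,
                     mesh$elements[, 4] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("10", m), con)
  if (!is.null(point_data) && length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      stopifnot(length(v) == n)
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default",
                   sprintf("%.17g", v)), con)
    }
  }
  invisible(path)
}

.read_vtk_mesh <- function(path) {
  lines <- readLines(path)
  toks <- function(s) strsplit(trimws(s), "\\s+")[[1]]
  ip <- grep("^POINTS", lines)[1]
  if (is.na(ip)) stop("not a legacy VTK unstructured grid: no POINTS section")
  n <- as.integer(toks(lines[ip])[2])
  pts <- scan(text = lines[(ip + 1):length(lines)], n = 3 * n, quiet = TRUE)
  nodes <- matrix(pts, ncol = 3, byrow = TRUE)
  ic <- grep("^CELLS", lines)[1]
  m <- as.integer(toks(lines[ic])[2])
  total <- as.integer(toks(lines[ic])[3])
  cells <- scan(text = lines[(ic + 1):length(lines)], n = total, quiet = TRUE)
  it <- grep("^CELL_TYPES", lines)[1]
  types <- scan(text = lines[(it + 1):length(lines)], n = m, quiet = TRUE)
  if (any(types != 10))
    stop("unsupported VTK cell types: only tetrahedra (type 10) are handled")
  conn <- matrix(0L, m, 4)
  pos <- 1L
  for (e in seq_len(m)) {
    k <- as.integer(cells[pos])
    if (k != 4L) stop("non-tetrahedral cell in VTK file")
    conn[e, ] <- as.integer(cells[(pos + 1L):(pos + 4L)]) + 1L # VTK is 0-based
    pos <- pos + 5L
  }
  tet_mesh(nodes, conn)
}

#' Persist a system matrix and measurements to a directory
#'
#' Writes `A.mtx` (Matrix Market), `phi_m.csv` (measurements),
#' `row_index.csv` (source id / detector node per row) and `meta.json`.
#'
#' @param sm a `system_matrix` (see [build_system_matrix()]).
#' @param y numeric measurement vector aligned with the rows of `sm$A`
#'   (optional).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_system <- function(sm, y = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(Matrix::Matrix(sm$A, sparse = TRUE),
                              "generalMatrix"),
                  file.path(dir, "A.mtx"))
  utils::write.csv(sm$row_index, file.path(dir, "row_index.csv"),
                   row.names = FALSE)
  if (!is.null(y)) {
    stopifnot(length(y) == nrow(sm$A))
    utils::write.csv(data.frame(phi_m = as.numeric(y)),
                     file.path(dir, "phi_m.csv"), row.names = FALSE)
  }
  jsonlite::write_json(list(rows = nrow(sm$A), cols = ncol(sm$A)),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Load a system matrix (and measurements) saved by [save_system()]
#'
#' @param dir directory containing `A.mtx` and friends.
#' @return list with `A` (dense matrix), `row_index`, and `y` (or `NULL`).
#' @export
load_system <- function(dir) {
  A <- as.matrix(Matrix::readMM(file.path(dir, "A.mtx")))
  row_index <- utils::read.csv(file.path(dir, "row_index.csv"))
  yf <- file.path(dir, "phi_m.csv")
  y <- if (file.exists(yf)) utils::read.csv(yf)$phi_m else NULL
  list(A = A, row_index = row_index, y = y)
}

#' Write a reconstruction as a nodal CSV
#'
#' @param solution a `sparse_solution` (see [nasols()]).
#' @param path output CSV path.
#' @param all_nodes if `TRUE` write every node, otherwise only the support.
#' @return `path`, invisibly.
#' @export
write_solution_csv <- function(solution, path, all_nodes = FALSE) {
  x <- solution$x_hat
  idx <- if (all_nodes) seq_along(x) else sort(solution$support)
  utils::write.csv(data.frame(node = idx, yield = x[idx]), path,
                   row.names = FALSE)
  invisible(path)
}
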