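# Greedy L0 solvers for the underdetermined FMT system Phi_m = A X.
#
# The core selection rule is orthogonal least squares: at iteration i each
# unselected column a_j keeps a deflated copy t_j, orthogonal to all
# previously accepted basis vectors u_1..u_i, and the candidate maximizing
#   || q_j ||_2,   q_j = (a_j' r / a_j' t_j) t_j
# is accepted; then u <- q_j, r <- r - u, and every deflated column is
# projected off u. NASOLS wraps this rule in an adaptive sparsity schedule
# (K_i grows, L_i shrinks, both by ceilinged (1/(i+1))^2 steps) and restricts
# candidates to the tetrahedral-edge neighbors of the current support.

#' Solver configuration
#'
#' @param K0 initial sparsity (columns kept in the final solution before the
#'   schedule grows it), >= 1.
#' @param L0 initial selection width (columns selected in the initial pass),
#'   >= 1.
#' @param eps halting threshold on the residual 2-norm, > 0.
#' @param eps_rel if `TRUE`, `eps` is relative to `||y||_2`; the default
#'   (`FALSE`) is an absolute threshold. Absolute thresholds interact with the
#'   arbitrary units of the measurements, so simulation drivers in this
#'   package use the relative mode.
#' @param max_iter cap on outer iterations, >= 1.
#' @param nonneg clamp the final coefficients at zero (fluorescent yield is
#'   nonnegative); off by default.
#' @param rescore if `FALSE` (default), each iteration selects the top-`L_i`
#'   candidates of a single scoring pass and then performs the residual and
#'   deflation updates per accepted column; `TRUE` re-scores the candidate
#'   set after every individual selection. The single-pass batch keeps
#'   correlated columns near a compact target together (with re-scoring, the
#'   initial batch degenerates to plain sequential OLS and the neighbor
#'   expansion loses its seeding advantage); the orthogonal basis is exact
#'   either way because the accepted projection is recomputed at update
#'   time.
#' @param stall_tol relative residual improvement below which an outer
#'   iteration counts as stalled and the adaptive solvers halt. With noisy or
#'   model-mismatched measurements the residual threshold `eps` is never
#'   reached and the support would otherwise grow until `max_iter`; stalling
#'   is the conventional stopping rule for pursuits with unknown sparsity.
#'   Set to 0 to disable.
#' @param tie_break tie-breaking rule for equal scores; only
#'   `"lowest-index"` is provided (deterministic across platforms).
#' @return object of class `solver_config`.
#' @export
solver_config <- function(K0 = 6L, L0 = 10L, eps = 1e-8, eps_rel = FALSE,
                          max_iter = 50L, nonneg = FALSE, rescore = FALSE,
                          stall_tol = 0.01, tie_break = "lowest-index") {
  K0 <- as.integer(K0); L0 <- as.integer(L0); max_iter <- as.integer(max_iter)
  if (is.na(K0) || K0 < 1L) stop("`K0` must be >= 1")
  if (is.na(L0) || L0 < 1L) stop("`L0` must be >= 1")
  if (!is.numeric(eps) || eps <= 0) stop("`eps` must be > 0")
  if (is.na(max_iter) || max_iter < 1L) stop("`max_iter` must be >= 1")
  if (!is.numeric(stall_tol) || stall_tol < 0 || stall_tol >= 1)
    stop("`stall_tol` must lie in [0, 1)")
  tie_break <- match.arg(tie_break, "lowest-index")
  structure(list(K0 = K0, L0 = L0, eps = eps, eps_rel = isTRUE(eps_rel),
                 max_iter = max_iter, nonneg = isTRUE(nonneg),
                 rescore = isTRUE(rescore), stall_tol = stall_tol,
                 tie_break = tie_break),
            class = "solver_config")
}

#' Adaptive sparsity schedule
#'
#' One step of the nonlinear schedule: the sparsity grows by
#' `ceiling(K0 / (i+1)^2)` and the selection width shrinks by
#' `ceiling(L0 / (i+1)^2)` (floored at 1, since a selection width of zero
#' would stall the algorithm). Steps are large early and settle to one per
#' iteration, so the estimated sparsity approaches the true one quickly.
#'
#' @param K_prev,L_prev values at iteration `i - 1`.
#' @param i iteration number, >= 1.
#' @param K0,L0 initial schedule parameters.
#' @return list with elements `K` and `L` (integers).
#' @examples
#' update_schedule(6, 10, i = 1, K0 = 6, L0 = 10) # K = 8, L = 7
#' @export
update_schedule <- function(K_prev, L_prev, i, K0, L0) {
  if (i < 1) stop("`i` must be >= 1")
  list(K = as.integer(K_prev + ceiling(K0 * (1 / (i + 1))^2)),
       L = as.integer(max(1, L_prev - ceiling(L0 * (1 / (i + 1))^2))))
}

# Scores, numerators and denominators for a candidate set. Candidates whose
# deflated direction is numerically exhausted (|a_j' t_j| below a relative
# floor) are excluded with score -Inf.
.score_batch <- function(A, deflated, r, candidates, colA2) {
  Asub <- A[, candidates, drop = FALSE]
  Tsub <- deflated[, candidates, drop = FALSE]
  num <- as.numeric(crossprod(Asub, r))
  den <- colSums(Asub * Tsub)
  tn2 <- colSums(Tsub^2)
  floorv <- 1e-12 * sqrt(colA2[candidates] * tn2)
  valid <- tn2 > 0 & abs(den) > floorv
  score <- rep(-Inf, length(candidates))
  score[valid] <- abs(num[valid] / den[valid]) * sqrt(tn2[valid])
  list(score = score, num = num, den = den)
}

#' Orthogonal least squares selection scores
#'
#' For each candidate column `j`, the score is `||q_j||_2` with
#' `q_j = (a_j' r / a_j' t_j) t_j`, where `t_j` is the column deflated
#' against the accepted orthogonal basis. Candidates whose `|a_j' t_j|` falls
#' below a relative numerical floor are excluded (score `-Inf`): their
#' direction is already exhausted by the basis.
#'
#' @param A system matrix (columns = atoms).
#' @param residual current residual vector.
#' @param deflated matrix of deflated columns `t_j` (same shape as `A`);
#'   defaults to `A` (fresh state, `t_j^0 = a_j`).
#' @param candidates integer vector of candidate column indices.
#' @return numeric vector of scores, named by candidate index.
#' @export
ols_scores <- function(A, residual, deflated = A,
                       candidates = seq_len(ncol(A))) {
  if (!length(candidates)) stop("`candidates` must be nonempty")
  sb <- .score_batch(as.matrix(A), as.matrix(deflated), as.numeric(residual),
                     as.integer(candidates), colSums(as.matrix(A)^2))
  if (all(!is.finite(sb$score)))
    stop("degenerate candidates: every candidate direction is exhausted")
  stats::setNames(sb$score, candidates)
}

#' Deflate columns against a new basis vector
#'
#' Projects every column of `deflated` off `u_new`:
#' `t_j <- t_j - (t_j' u / ||u||^2) u`. Afterwards every column is orthogonal
#' to `u_new` (to roundoff).
#'
#' @param deflated matrix of deflated column vectors (or a single vector).
#' @param u_new the just-accepted orthogonal basis vector; must be nonzero.
#' @return the updated matrix (or vector).
#' @export
deflate_columns <- function(deflated, u_new) {
  u_new <- as.numeric(u_new)
  u2 <- sum(u_new^2)
  if (u2 == 0) stop("degenerate basis: `u_new` has zero norm")
  vec <- is.null(dim(deflated))
  Tm <- if (vec) matrix(deflated, ncol = 1) else deflated
  Tm <- Tm - u_new %*% (crossprod(u_new, Tm) / u2)
  if (vec) as.numeric(Tm) else Tm
}

#' Residual update
#'
#' Accepts the selected projection `q_j` as the next orthogonal basis vector
#' and removes it from the residual: `u <- q_j`, `r <- r - u`.
#'
#' @param residual current residual vector.
#' @param q_selected the `q_j` of the just-selected column.
#' @return list with `residual` (updated) and `u` (the new basis vector).
#' @export
update_residual <- function(residual, q_selected) {
  list(residual = as.numeric(residual) - as.numeric(q_selected),
       u = as.numeric(q_selected))
}

#' Least squares restricted to a support
#'
#' Minimizes `||A[, support] c - y||_2` by rank-revealing QR. Directions of
#' the restricted matrix whose relative pivot falls below `tol` are treated
#' as numerically dependent -- greedy supports on fine meshes often contain
#' near-identical columns, and amplifying such directions only fits noise --
#' and the minimum-norm solution over the well-conditioned subspace is
#' returned (with a warning).
#'
#' @param A system matrix.
#' @param support nonempty integer vector of column indices.
#' @param y measurement vector.
#' @param tol relative rank tolerance.
#' @return list with `coefficients` (aligned with `support`),
#'   `residual_norm`, and `rank`.
#' @export
restricted_lsq <- function(A, support, y, tol = 1e-8) {
  support <- as.integer(support)
  if (!length(support)) stop("`support` must be nonempty")
  As <- as.matrix(A)[, support, drop = FALSE]
  y <- as.numeric(y)
  sv <- svd(As)
  pos <- sv$d > tol * sv$d[1]
  rank <- sum(pos)
  if (rank < ncol(As))
    warning("numerically rank-deficient support; ",
            "returning the minimum-norm solution")
  coef <- as.numeric(sv$v[, pos, drop = FALSE] %*%
                       (crossprod(sv$u[, pos, drop = FALSE], y) /
                          sv$d[pos]))
  list(coefficients = coef,
       residual_norm = sqrt(sum((y - As %*% coef)^2)),
       rank = rank)
}

.norm2 <- function(v) sqrt(sum(v^2))

# Shared engine for NASOLS (graph-restricted candidates) and ASOLS
# (graph = NULL, candidates = all unselected columns).
.greedy_adaptive <- function(A, y, graph = NULL, config, method) {
  A <- as.matrix(A)
  y <- as.numeric(y)
  m <- nrow(A); n <- ncol(A)
  if (length(y) != m) stop("length(y) must equal nrow(A)")
  if (!is.null(graph) && graph$n_nodes != n)
    stop("column count of A (", n, ") must equal the node count of the ",
         "neighbor graph (", graph$n_nodes, ")")
  eps <- if (config$eps_rel) config$eps * .norm2(y) else config$eps
  Tm <- A
  r <- y
  colA2 <- colSums(A^2)
  S <- integer(0)
  U <- vector("list", 0)
  sel_cap <- min(m, n)
  K <- config$K0
  L <- config$L0
  hist <- list()

  # one OLS selection among `cand`; returns selected index or NA
  select_one <- function(cand) {
    sb <- .score_batch(A, Tm, r, cand, colA2)
    best <- which.max(sb$score) # first max: lowest-index tie-break
    if (!length(best) || !is.finite(sb$score[best]) || sb$score[best] <= 0)
      return(NA_integer_)
    j <- cand[best]
    q <- (sb$num[best] / sb$den[best]) * Tm[, j]
    u2 <- sum(q^2)
    if (u2 == 0) return(NA_integer_)
    r <<- r - q
    Tm <<- Tm - q %*% (crossprod(q, Tm) / u2)
    U[[length(U) + 1L]] <<- q
    S <<- c(S, j)
    j
  }

  # up to L_batch selections from `cand`, re-scoring (default) or single-pass
  select_batch <- function(cand, L_batch) {
    nsel <- 0L
    if (L_batch < 1L || !length(cand)) return(nsel)
    if (config$rescore) {
      for (k in seq_len(L_batch)) {
        if (.norm2(r) <= eps) break
        j <- select_one(cand)
        if (is.na(j)) break
        cand <- cand[cand != j]
        nsel <- nsel + 1L
        if (!length(cand)) break
      }
    } else {
      sb <- .score_batch(A, Tm, r, cand, colA2)
      ord <- order(-sb$score, cand)
      picks <- cand[ord[is.finite(sb$score[ord]) & sb$score[ord] > 0]]
      picks <- utils::head(picks, L_batch)
      for (j in picks) {
        if (.norm2(r) <= eps) break
        if (!is.na(select_one(j))) nsel <- nsel + 1L
      }
    }
    nsel
  }

  converged <- TRUE
  if (.norm2(r) > eps) {
    # initial support: L0 columns chosen from all columns by the OLS score
    select_batch(seq_len(n), min(config$L0, sel_cap))
    hist[[1]] <- data.frame(iter = 0L, K = K, L = L,
                            residual_norm = .norm2(r),
                            support_size = length(S))
    i <- 1L
    repeat {
      if (.norm2(r) <= eps) { converged <- TRUE; break }
      if (length(S) >= sel_cap) { converged <- .norm2(r) <= eps; break }
      if (i > config$max_iter) { converged <- FALSE; break }
      sch <- update_schedule(K, L, i, config$K0, config$L0)
      K <- min(sch$K, sel_cap)
      L <- sch$L
      cand <- if (is.null(graph)) setdiff(seq_len(n), S)
              else neighbor_set(graph, S)
      if (!length(cand)) { converged <- FALSE; break }
      rn_before <- .norm2(r)
      nsel <- select_batch(cand, min(L, sel_cap - length(S)))
      rn_after <- .norm2(r)
      hist[[length(hist) + 1L]] <- data.frame(iter = i, K = K, L = L,
                                              residual_norm = rn_after,
                                              support_size = length(S))
      if (nsel == 0L) { converged <- rn_after <= eps; break }
      if (rn_before - rn_after < config$stall_tol * rn_before) {
        converged <- rn_after <= eps
        break
      }
      i <- i + 1L
    }
  } else {
    i <- 0L
  }

  .finish_solution(A, y, S, K, config, method,
                   iterations = i, converged = converged,
                   history = do.call(rbind, hist),
                   basis = if (length(U)) do.call(cbind, U) else
                     matrix(0, m, 0),
                   attained = list(eps = eps, residual = .norm2(r),
                                   converged = converged))
}

# Restricted least squares on the first K_final selected columns, zero
# elsewhere; the universal convention for OLS/OMP-family estimates. If the
# truncated support cannot attain the residual the full selection achieved
# (a true atom was selected late in a batch), the support is extended along
# the selection order until it does.
.finish_solution <- function(A, y, S, K_final, config, method, iterations,
                             converged, history = NULL, basis = NULL,
                             attained = NULL) {
  n <- ncol(A)
  x <- numeric(n)
  K_final <- min(K_final, length(S))
  support <- S[seq_len(K_final)]
  coef <- numeric(0)
  if (K_final > 0L) {
    ls <- suppressWarnings(restricted_lsq(A, support, y))
    if (!is.null(attained) && isTRUE(attained$converged)) {
      # the halting condition was met by the full selection; the reported
      # support must meet it too, so extend along the selection order until
      # the truncated fit reaches the attained residual
      thr <- max(attained$eps, attained$residual * (1 + 1e-9))
      while (ls$residual_norm > thr && K_final < length(S)) {
        K_final <- K_final + 1L
        support <- S[seq_len(K_final)]
        ls <- suppressWarnings(restricted_lsq(A, support, y))
      }
    }
    coef <- ls$coefficients
    if (config$nonneg) coef <- pmax(coef, 0)
    x[support] <- coef
  }
  structure(list(x_hat = x,
                 support = support,
                 selected = S,
                 coefficients = coef,
                 residual_norm = .norm2(y - A %*% x),
                 iterations = iterations,
                 converged = converged,
                 history = history,
                 basis = basis,
                 method = method,
                 config = config),
            class = "sparse_solution")
}

#' @export
print.sparse_solution <- function(x, ...) {
  cat(sprintf("%s solution: %d nonzero nodes, residual %.4g, %d iterations%s\n",
              x$method, length(x$support), x$residual_norm, x$iterations,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' NASOLS: neighbor-based adaptive sparsity orthogonal least squares
#'
#' Solves `min ||x||_0 s.t. ||A x - y||_2 < eps` without a sparsity prior.
#' The initial support takes the `L0` best columns by the OLS score; each
#' subsequent iteration updates the schedule `(K_i, L_i)`, restricts
#' candidates to the tetrahedral-edge neighbors `N(S_i)` of the current
#' support (preserving the local spatial structure of a compact fluorescent
#' target), selects up to `L_i` of them by the OLS score, and orthogonalizes
#' residual and columns. On halting, the final estimate is the restricted
#' least-squares fit on the first `K_i` selected columns.
#'
#' @param A system matrix (rows = measurements, columns = mesh nodes).
#' @param y measurement vector.
#' @param graph the mesh [edge_adjacency()] graph; its node count must equal
#'   `ncol(A)`.
#' @param config a [solver_config()].
#' @return a `sparse_solution`: `x_hat` (nodal yield estimate), `support`
#'   (final support, selection order), `selected` (all selected columns),
#'   `residual_norm`, `iterations`, `converged`, per-iteration `history`
#'   (`K_i`, `L_i`, `||r_i||`), and the orthogonal `basis`.
#' @seealso [asols()] for the variant without the neighbor restriction,
#'   [ols_fixed()], [omp()], [gomp()], [cosamp()] for fixed-sparsity
#'   baselines.
#' @export
nasols <- function(A, y, graph, config = solver_config()) {
  if (!inherits(graph, "neighbor_graph"))
    stop("`graph` must be a neighbor_graph from edge_adjacency()")
  .greedy_adaptive(A, y, graph, config, "NASOLS")
}

#' ASOLS: adaptive sparsity orthogonal least squares
#'
#' Identical to [nasols()] except that every unselected column is a candidate
#' at every iteration (no neighbor restriction); equivalently, NASOLS on a
#' complete graph.
#'
#' @inheritParams nasols
#' @return a `sparse_solution`.
#' @export
asols <- function(A, y, config = solver_config()) {
  .greedy_adaptive(A, y, NULL, config, "ASOLS")
}

#' Fixed-sparsity orthogonal least squares
#'
#' `K` iterations of single-column OLS selection with column deflation,
#' followed by restricted least squares on the selected support. This is the
#' classical baseline that needs the sparsity `K` supplied manually.
#'
#' @inheritParams nasols
#' @param K number of columns to select, between 1 and `ncol(A)`.
#' @param eps,eps_rel halting threshold (see [solver_config()]).
#' @param nonneg clamp final coefficients at zero.
#' @return a `sparse_solution`.
#' @export
ols_fixed <- function(A, y, K, eps = 1e-8, eps_rel = FALSE, nonneg = FALSE) {
  A <- as.matrix(A)
  y <- as.numeric(y)
  m <- nrow(A); n <- ncol(A)
  K <- as.integer(K)
  if (K < 1L || K > n) stop("`K` must lie in 1..ncol(A)")
  config <- solver_config(K0 = K, L0 = 1L, eps = eps, eps_rel = eps_rel,
                          nonneg = nonneg)
  eps_eff <- if (config$eps_rel) eps * .norm2(y) else eps
  Tm <- A
  r <- y
  colA2 <- colSums(A^2)
  S <- integer(0)
  U <- list()
  hist <- list()
  it <- 0L
  while (length(S) < K && .norm2(r) > eps_eff) {
    it <- it + 1L
    cand <- setdiff(seq_len(n), S)
    sb <- .score_batch(A, Tm, r, cand, colA2)
    best <- which.max(sb$score)
    if (!is.finite(sb$score[best]) || sb$score[best] <= 0) {
      warning("OLS stopped after ", length(S), " of ", K,
              " selections: remaining columns are exhausted")
      break
    }
    j <- cand[best]
    q <- (sb$num[best] / sb$den[best]) * Tm[, j]
    r <- r - q
    Tm <- Tm - q %*% (crossprod(q, Tm) / sum(q^2))
    U[[length(U) + 1L]] <- q
    S <- c(S, j)
    hist[[it]] <- data.frame(iter = it, K = K, L = 1L,
                             residual_norm = .norm2(r),
                             support_size = length(S))
  }
  .finish_solution(A, y, S, length(S), config, "OLS",
                   iterations = it, converged = .norm2(r) <= eps_eff ||
                     length(S) == K,
                   history = do.call(rbind, hist),
                   basis = if (length(U)) do.call(cbind, U) else
                     matrix(0, m, 0))
}

# Correlation proxy used by the matching-pursuit family (column-normalized).
.mp_proxy <- function(A, r, colnorm) {
  p <- abs(as.numeric(crossprod(A, r)))
  p[colnorm > 0] <- p[colnorm > 0] / colnorm[colnorm > 0]
  p[colnorm == 0] <- 0
  p
}

#' Orthogonal matching pursuit
#'
#' One maximum-correlation atom per iteration, restricted least squares on
#' the running support, residual update; halts at `K` atoms or when the
#' residual drops below `eps`.
#'
#' @inheritParams ols_fixed
#' @return a `sparse_solution`.
#' @export
omp <- function(A, y, K, eps = 1e-8, eps_rel = FALSE, nonneg = FALSE) {
  .mp_engine(A, y, K, n_per_iter = 1L, eps = eps, eps_rel = eps_rel,
             nonneg = nonneg, method = "OMP")
}

#' Generalized orthogonal matching pursuit
#'
#' Selects the `n_per_iter` largest correlations per iteration (capped so the
#' support never exceeds `K`), otherwise as [omp()].
#'
#' @inheritParams ols_fixed
#' @param n_per_iter atoms selected per iteration, >= 1.
#' @return a `sparse_solution`.
#' @export
gomp <- function(A, y, K, n_per_iter = 3L, eps = 1e-8, eps_rel = FALSE,
                 nonneg = FALSE) {
  if (n_per_iter < 1L) stop("`n_per_iter` must be >= 1")
  .mp_engine(A, y, K, n_per_iter = as.integer(n_per_iter), eps = eps,
             eps_rel = eps_rel, nonneg = nonneg, method = "gOMP")
}

.mp_engine <- function(A, y, K, n_per_iter, eps, eps_rel, nonneg, method) {
  A <- as.matrix(A)
  y <- as.numeric(y)
  n <- ncol(A)
  K <- as.integer(K)
  if (K < 1L || K > n) stop("`K` must lie in 1..ncol(A)")
  config <- solver_config(K0 = K, L0 = n_per_iter, eps = eps,
                          eps_rel = eps_rel, nonneg = nonneg)
  eps_eff <- if (eps_rel) eps * .norm2(y) else eps
  colnorm <- sqrt(colSums(A^2))
  r <- y
  S <- integer(0)
  hist <- list()
  it <- 0L
  while (length(S) < K && .norm2(r) > eps_eff) {
    it <- it + 1L
    proxy <- .mp_proxy(A, r, colnorm)
    proxy[S] <- -Inf
    take <- min(n_per_iter, K - length(S))
    picks <- order(-proxy, seq_len(n))[seq_len(take)]
    picks <- picks[is.finite(proxy[picks]) & proxy[picks] > 0]
    if (!length(picks)) break
    S <- c(S, picks)
    ls <- restricted_lsq(A, S, y)
    r <- y - A[, S, drop = FALSE] %*% ls$coefficients
    hist[[it]] <- data.frame(iter = it, K = K, L = length(picks),
                             residual_norm = .norm2(r),
                             support_size = length(S))
  }
  .finish_solution(A, y, S, length(S), config, method,
                   iterations = it,
                   converged = .norm2(r) <= eps_eff || length(S) == K,
                   history = do.call(rbind, hist))
}

#' Compressive sampling matching pursuit (CoSaMP)
#'
#' Per iteration: identify the `2K` strongest correlations, merge with the
#' current support, solve restricted least squares on the merged set, prune
#' to the `K` largest coefficients, and update the residual. Backtracking
#' lets earlier selections be revised. Halts on `eps`, `max_iter`, or
#' residual stagnation (a step that fails to decrease the residual is
#' rejected).
#'
#' @inheritParams ols_fixed
#' @param max_iter iteration cap.
#' @return a `sparse_solution`.
#' @export
cosamp <- function(A, y, K, eps = 1e-8, eps_rel = FALSE, nonneg = FALSE,
                   max_iter = 50L) {
  A <- as.matrix(A)
  y <- as.numeric(y)
  m <- nrow(A); n <- ncol(A)
  K <- as.integer(K)
  if (K < 1L || K > n) stop("`K` must lie in 1..ncol(A)")
  if (3L * K > m)
    warning("CoSaMP merged supports (3K = ", 3 * K, ") exceed the ",
            m, " measurements; least-squares steps may be rank deficient")
  config <- solver_config(K0 = K, L0 = 2L * K, eps = eps, eps_rel = eps_rel,
                          nonneg = nonneg, max_iter = max_iter)
  eps_eff <- if (eps_rel) eps * .norm2(y) else eps
  colnorm <- sqrt(colSums(A^2))
  S <- integer(0)
  x <- numeric(n)
  r <- y
  hist <- list()
  it <- 0L
  while (it < max_iter && .norm2(r) > eps_eff) {
    it <- it + 1L
    proxy <- .mp_proxy(A, r, colnorm)
    omega <- order(-proxy, seq_len(n))[seq_len(min(2L * K, n))]
    omega <- omega[proxy[omega] > 0]
    merged <- sort(union(S, omega))
    if (!length(merged)) break
    ls <- suppressWarnings(restricted_lsq(A, merged, y))
    b <- ls$coefficients
    keep <- order(-abs(b), merged)[seq_len(min(K, length(merged)))]
    S_new <- merged[keep]
    x_new <- numeric(n)
    x_new[S_new] <- b[keep]
    r_new <- y - A %*% x_new
    if (.norm2(r_new) > .norm2(r) * (1 - 1e-9)) break # stagnation: reject
    S <- S_new
    x <- x_new
    r <- as.numeric(r_new)
    hist[[length(hist) + 1L]] <- data.frame(iter = it, K = K, L = 2L * K,
                                            residual_norm = .norm2(r),
                                            support_size = length(S))
  }
  # report the support in decreasing coefficient magnitude
  S <- S[order(-abs(x[S]), S)]
  .finish_solution(A, y, S, length(S), config, "CoSaMP",
                   iterations = it,
                   converged = .norm2(r) <= eps_eff || length(S) == K,
                   history = do.call(rbind, hist))
}
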