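test_that("solver configuration is validated", {
  expect_error(solver_config(K0 = 0), "K0")
  expect_error(solver_config(L0 = 0), "L0")
  expect_error(solver_config(eps = 0), "eps")
  expect_error(solver_config(max_iter = 0), "max_iter")
  expect_error(solver_config(stall_tol = 1), "stall_tol")
})

test_that("adaptive schedule follows the ceilinged quadratic-decay steps", {
  s1 <- update_schedule(6, 10, i = 1, K0 = 6, L0 = 10)
  expect_identical(s1, list(K = 8L, L = 7L))
  s2 <- update_schedule(s1$K, s1$L, i = 2, K0 = 6, L0 = 10)
  expect_identical(s2, list(K = 9L, L = 5L))
  # late iterations: K grows by exactly 1, L floors at 1
  K <- 6L; L <- 10L
  for (i in 1:60) {
    s <- update_schedule(K, L, i, 6, 10)
    expect_gt(s$K, K)
    expect_lte(s$L, L)
    K <- s$K; L <- s$L
  }
  expect_identical(L, 1L)
  expect_identical(update_schedule(K, L, 61, 6, 10)$K, K + 1L)
  expect_error(update_schedule(6, 10, i = 0, 6, 10), "i")
})

test_that("OLS scores reproduce hand-evaluated selection criteria", {
  # orthonormal columns reduce the criterion to |a_j' r|
  sc <- ols_scores(diag(3), residual = c(0, 5, 0))
  expect_equal(unname(which.max(sc)), 2L)
  expect_equal(unname(sc), c(0, 5, 0))

  A <- cbind(c(1, 0), c(0.6, 0.8))
  sc2 <- ols_scores(A, residual = c(1, 0))
  expect_equal(unname(sc2), c(1.0, 0.6), tolerance = 1e-12)

  expect_equal(unname(ols_scores(A, residual = c(0, 0))), c(0, 0))
  expect_error(ols_scores(A, residual = c(1, 0), candidates = integer(0)),
               "nonempty")
  # exhausted directions are excluded
  expect_error(ols_scores(A, residual = c(1, 0),
                          deflated = matrix(0, 2, 2)),
               "degenerate")
})

test_that("column deflation projects off the accepted basis vector", {
  u <- c(1, 2, 2)
  expect_equal(deflate_columns(3 * u, u), c(0, 0, 0), tolerance = 1e-12)
  v <- c(2, -1, 0) # orthogonal to u
  expect_equal(deflate_columns(v, u), v, tolerance = 1e-12)
  set.seed(1)
  Tm <- matrix(rnorm(10 * 6), 10)
  u10 <- rnorm(10)
  Td <- deflate_columns(Tm, u10)
  expect_lt(max(abs(crossprod(Td, u10))), 1e-12)
  expect_error(deflate_columns(Tm, rep(0, 10)), "zero norm")
})

test_that("residual update removes the accepted projection", {
  up <- update_residual(c(0, 5, 0), c(0, 5, 0))
  expect_equal(up$residual, c(0, 0, 0))
  expect_equal(up$u, c(0, 5, 0))
})

test_that("restricted least squares matches direct solves", {
  set.seed(2)
  A <- matrix(rnorm(16), 4)
  y <- rnorm(4)
  ls <- restricted_lsq(A, 1:4, y)
  expect_equal(ls$coefficients, as.numeric(solve(A, y)), tolerance = 1e-10)
  expect_lt(ls$residual_norm, 1e-10)

  # support disjoint from the signal, orthogonal columns
  ls2 <- restricted_lsq(diag(3), 1, c(0, 1, 0))
  expect_equal(ls2$coefficients, 0)
  expect_equal(ls2$residual_norm, 1)

  # tall system vs normal-equations oracle
  A3 <- matrix(rnorm(30 * 5), 30)
  y3 <- rnorm(30)
  ls3 <- restricted_lsq(A3, 1:5, y3)
  oracle <- solve(crossprod(A3), crossprod(A3, y3))
  expect_equal(ls3$coefficients, as.numeric(oracle), tolerance = 1e-10)

  # duplicated column: minimum-norm with a warning
  A4 <- cbind(c(1, 0), c(1, 0))
  expect_warning(ls4 <- restricted_lsq(A4, 1:2, c(2, 0)), "rank-deficient")
  expect_equal(ls4$coefficients, c(1, 1), tolerance = 1e-10)
})

test_that("trivial instances are solved exactly", {
  g <- complete_graph(6)
  s0 <- nasols(diag(6), rep(0, 6), g)
  expect_equal(s0$x_hat, rep(0, 6))
  expect_lte(length(s0$selected), 10)
  expect_true(s0$converged)

  # identity matrix on a path graph, unit impulse at node 5
  path <- structure(list(adjacency = lapply(1:10, function(i)
    intersect(c(i - 1L, i + 1L), 1:10)), n_nodes = 10L),
    class = "neighbor_graph")
  e5 <- replace(numeric(10), 5, 1)
  s <- nasols(diag(10), e5, path, solver_config(K0 = 1, L0 = 1))
  expect_identical(s$support, 5L)
  expect_equal(s$x_hat, e5)
  expect_lt(s$residual_norm, 1e-12)

  sa <- asols(diag(10), e5, solver_config(K0 = 1, L0 = 1))
  expect_identical(sa$support, 5L)

  for (solver in list(function(A, y) omp(A, y, 2),
                      function(A, y) gomp(A, y, 2),
                      function(A, y) cosamp(A, y, 2))) {
    sz <- solver(diag(6), rep(0, 6))
    expect_equal(sz$x_hat, rep(0, 6))
  }
})

test_that("noiseless cluster-sparse signals are recovered exactly", {
  m <- jittered_grid_mesh(c(4L, 4L, 7L), seed = 3) # 200 nodes
  g <- edge_adjacency(m)
  A <- unit_gauss_A(64, 200, seed = 21)
  sup <- connected_support(g, 4, seed = 22)
  x0 <- numeric(200)
  x0[sup] <- runif(4, 0.5, 2)
  y <- as.numeric(A %*% x0)
  s <- nasols(A, y, g)
  expect_true(all(sup %in% s$support))
  expect_lt(rel_err(s$x_hat, x0), 1e-6)
  sa <- asols(A, y)
  expect_lt(rel_err(sa$x_hat, x0), 1e-6)
})

test_that("NASOLS on the complete graph reproduces ASOLS exactly", {
  set.seed(31)
  A <- unit_gauss_A(20, 40)
  x0 <- numeric(40); x0[c(3, 17, 25)] <- c(1, -2, 1.5)
  y <- as.numeric(A %*% x0) + 0.01 * rnorm(20)
  cfg <- solver_config()
  sn <- nasols(A, y, complete_graph(40), cfg)
  sa <- asols(A, y, cfg)
  expect_identical(sn$support, sa$support)
  expect_identical(sn$x_hat, sa$x_hat)
  expect_identical(sn$history$residual_norm, sa$history$residual_norm)
})

test_that("fixed-sparsity OLS matches its classical behavior", {
  # K = column count on a square invertible system: exact solve
  set.seed(4)
  A <- matrix(rnorm(25), 5)
  y <- rnorm(5)
  s <- ols_fixed(A, y, K = 5)
  expect_lt(s$residual_norm, 1e-8)

  # orthonormal columns: selections are the K largest |a_j' y| in order
  Q <- qr.Q(qr(matrix(rnorm(36), 6)))
  y6 <- rnorm(6)
  s2 <- ols_fixed(Q, y6, K = 4)
  expect_identical(s2$selected, order(-abs(crossprod(Q, y6)))[1:4])

  # two-column hand example
  A2 <- cbind(c(1, 0), c(0.6, 0.8))
  expect_identical(ols_fixed(A2, c(1, 0), K = 1)$support, 1L)

  expect_error(ols_fixed(A2, c(1, 0), K = 3), "1..ncol")
})

test_that("matching-pursuit family agrees with OLS on orthonormal columns", {
  set.seed(6)
  Q <- qr.Q(qr(matrix(rnorm(64), 8)))
  y <- rnorm(8)
  k <- 3
  expect_setequal(omp(Q, y, k)$support, ols_fixed(Q, y, k)$support)
  expect_setequal(gomp(Q, y, k, n_per_iter = 1)$support,
                  ols_fixed(Q, y, k)$support)
})

test_that("CoSaMP recovers exact-sparse supports on incoherent systems", {
  set.seed(8)
  hits <- 0
  for (t in 1:10) {
    A <- unit_gauss_A(20, 30)
    sup <- sample(30, 3)
    x0 <- numeric(30); x0[sup] <- runif(3, 1, 2) * sample(c(-1, 1), 3, TRUE)
    s <- suppressWarnings(cosamp(A, as.numeric(A %*% x0), 3))
    if (setequal(s$support, sup)) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("residuals are monotone and bases orthogonal for every solver", {
  set.seed(9)
  for (t in 1:5) {
    A <- unit_gauss_A(20, 50)
    x0 <- numeric(50); x0[sample(50, 4)] <- rnorm(4)
    y <- as.numeric(A %*% x0) + 0.05 * rnorm(20)
    sols <- list(nasols(A, y, complete_graph(50)),
                 asols(A, y),
                 ols_fixed(A, y, 5),
                 omp(A, y, 5),
                 gomp(A, y, 5),
                 suppressWarnings(cosamp(A, y, 5)))
    for (s in sols) {
      rn <- c(sqrt(sum(y^2)), s$history$residual_norm)
      expect_true(all(diff(rn) <= 1e-10 * rn[1]))
    }
    for (s in sols[1:3]) { # OLS family exposes the orthogonal basis
      U <- s$basis
      if (ncol(U) >= 2) {
        Gm <- abs(crossprod(U))
        nm <- sqrt(diag(Gm))
        off <- Gm / outer(nm, nm)
        diag(off) <- 0
        expect_lt(max(off), 1e-8)
      }
    }
  }
})

test_that("solutions are scale equivariant (with the threshold rescaled)", {
  set.seed(10)
  A <- unit_gauss_A(15, 30)
  x0 <- numeric(30); x0[c(2, 9)] <- c(1, -1)
  y <- as.numeric(A %*% x0) + 0.02 * rnorm(15)
  c0 <- 1e-6
  s1 <- asols(A, y, solver_config(eps = 1e-8))
  s2 <- asols(c0 * A, c0 * y, solver_config(eps = 1e-8 * c0))
  expect_identical(s1$support, s2$support)
  expect_equal(s1$x_hat, s2$x_hat, tolerance = 1e-9)
  # relative mode needs no rescaling at all
  s3 <- asols(A, y, solver_config(eps_rel = TRUE))
  s4 <- asols(c0 * A, c0 * y, solver_config(eps_rel = TRUE))
  expect_identical(s3$support, s4$support)
})

test_that("dimension mismatches are rejected", {
  A <- unit_gauss_A(10, 20, seed = 1)
  expect_error(nasols(A, rnorm(9), complete_graph(20)), "nrow")
  expect_error(nasols(A, rnorm(10), complete_graph(19)), "node count")
})
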