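test_that("weighted centroid averages node positions by intensity", {
  m <- generate_cube_mesh(10, 5)
  x <- numeric(n_nodes(m))
  x[5] <- 2
  expect_equal(weighted_centroid(x, 5, m), as.numeric(m$nodes[5, ]))
  x[6] <- 2
  expect_equal(weighted_centroid(x, c(5, 6), m),
               as.numeric((m$nodes[5, ] + m$nodes[6, ]) / 2))
  # weights 1 and 3 at (0,0,0) and (4,0,0) -> (3,0,0)
  m2 <- tet_mesh(rbind(c(0, 0, 0), c(4, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                 matrix(1:4, 1))
  expect_equal(weighted_centroid(c(1, 3, 0, 0), c(1, 2), m2), c(3, 0, 0))
  expect_error(weighted_centroid(c(0, 0, 0, 0), 1:2, m2), "weight")
})

test_that("location error is the Euclidean metric", {
  expect_equal(location_error(c(1, 2, 3), c(1, 2, 3)), 0)
  a <- c(17.51, 12.16, 16.65); b <- c(18.0, 12.0, 16.4)
  expect_equal(location_error(a, b), location_error(b, a))
  set.seed(12)
  for (t in 1:20) {
    p <- rnorm(3); q <- rnorm(3); r <- rnorm(3)
    expect_lte(location_error(p, r),
               location_error(p, q) + location_error(q, r) + 1e-12)
  }
})

test_that("published center tables recompute to their printed LE values", {
  true_single <- c(18.0, 12.0, 16.4)
  expect_equal(round(location_error(c(17.51, 12.16, 16.65), true_single), 2),
               0.57)
  expect_equal(round(location_error(c(18.32, 12.18, 17.03), true_single), 2),
               0.73)
})

test_that("NRMSE normalizes by the true dynamic range", {
  N <- 50
  xt <- numeric(N); xt[7] <- 0.05
  expect_equal(nrmse(xt, xt), 0)
  expect_equal(nrmse(numeric(N), xt), 1 / sqrt(N))
  xr <- xt + 0.001
  expect_equal(nrmse(3 * xr, 3 * xt), nrmse(xr, xt))
  expect_error(nrmse(xr, rep(1, N)), "constant")
  expect_error(nrmse(xr[1:10], xt), "same mesh")
})

test_that("CNR uses node-fraction-weighted pooled population variance", {
  x <- c(1, 1, 3, 3, 0, 0, 0, 2)
  expect_equal(cnr(x, roi = 1:4), 1.5 / sqrt(0.875), tolerance = 1e-12)
  expect_equal(cnr(5 * x, roi = 1:4), cnr(x, roi = 1:4))
  expect_error(cnr(rep(1, 8), roi = 1:4), "zero pooled variance")
  expect_error(cnr(x, roi = 1:8), "nonempty")
})

test_that("evaluation matches clusters to targets and flags collapses", {
  m <- generate_cube_mesh(20, 2.5)
  g <- edge_adjacency(m)
  targets <- list(target_spec(c(5, 10, 10), 1.5, 0.05),
                  target_spec(c(15, 10, 10), 1.5, 0.05))
  xt <- make_yield_phantom(m, targets)

  # perfect reconstruction: both targets resolved at LE 0
  rep1 <- evaluate_reconstruction(xt, xt, targets, m, g)
  expect_true(rep1$resolved)
  expect_equal(rep1$n_components, 2L)
  expect_equal(rep1$per_target$le, c(0, 0), tolerance = 1e-9)
  expect_equal(rep1$nrmse, 0)

  # collapse onto one target: the other is unmatched (LE absent)
  xc <- make_yield_phantom(m, targets[1], warn = FALSE)
  rep2 <- evaluate_reconstruction(xc, xt, targets, m, g)
  expect_false(rep2$resolved)
  expect_equal(rep2$n_components, 1L)
  expect_equal(sum(is.na(rep2$per_target$le)), 1L)
  expect_equal(rep2$per_target$le[1], 0, tolerance = 1e-9)

  # empty reconstruction
  rep3 <- evaluate_reconstruction(numeric(n_nodes(m)), xt, targets, m, g)
  expect_equal(rep3$n_components, 0L)
  expect_true(all(is.na(rep3$per_target$le)))
})

test_that("matching pairs each center with its nearest true center", {
  # worked double-target example: published phantom centers
  m <- generate_cube_mesh(25, 2.5)
  g <- edge_adjacency(m)
  true1 <- c(5.0, 15.0, 15.0); true2 <- c(5.0, 10.0, 15.0)
  rec1 <- c(4.48, 14.92, 15.44); rec2 <- c(5.36, 10.65, 14.70)
  targets <- list(target_spec(true1, 1, 0.05, shape = "cylinder", height = 2),
                  target_spec(true2, 1, 0.05, shape = "cylinder", height = 2))
  x <- numeric(n_nodes(m))
  x[which.min(colSums((t(m$nodes) - rec1)^2))] <- 0.05
  x[which.min(colSums((t(m$nodes) - rec2)^2))] <- 0.04
  xt <- make_yield_phantom(m, targets)
  rep <- evaluate_reconstruction(x, xt, targets, m, g)
  expect_true(rep$resolved)
  # rec1 pairs with true1, rec2 with true2 (nearest-centroid matching)
  expect_lt(rep$per_target$le[1], location_error(rec2, true1))
  expect_lt(rep$per_target$le[2], location_error(rec1, true2))
})

test_that("evaluation is invariant under target permutation", {
  m <- generate_cube_mesh(20, 2.5)
  g <- edge_adjacency(m)
  targets <- list(target_spec(c(5, 10, 10), 1.5, 0.05),
                  target_spec(c(15, 10, 10), 1.5, 0.05))
  xt <- make_yield_phantom(m, targets)
  set.seed(14)
  x <- xt + 0.002 * runif(length(xt))
  r1 <- evaluate_reconstruction(x, xt, targets, m, g)
  r2 <- evaluate_reconstruction(x, xt, rev(targets), m, g)
  expect_equal(sort(r1$per_target$le), sort(r2$per_target$le))
  expect_equal(r1$nrmse, r2$nrmse)
  expect_equal(r1$cnr, r2$cnr)
})

test_that("all indicators improve when truth replaces a noisy estimate", {
  m <- generate_cube_mesh(20, 2.5)
  g <- edge_adjacency(m)
  set.seed(15)
  for (t in 1:3) {
    ctr <- runif(3, 6, 14)
    targets <- list(target_spec(ctr, 2, 0.05))
    xt <- make_yield_phantom(m, targets)
    noise <- rnorm(length(xt))
    x <- pmax(xt + 0.01 * noise, 0)
    x_good <- pmax(xt + 0.0005 * noise, 0)
    bad <- evaluate_reconstruction(x, xt, targets, m, g)
    good <- evaluate_reconstruction(x_good, xt, targets, m, g)
    expect_lte(good$per_target$le, bad$per_target$le)
    expect_lte(good$nrmse, bad$nrmse)
    expect_gte(good$cnr, bad$cnr)
  }
})

test_that("report tables carry the center/LE/NRMSE/CNR column order", {
  m <- generate_cube_mesh(20, 5)
  g <- edge_adjacency(m)
  targets <- list(target_spec(c(10, 10, 10), 3, 0.05))
  xt <- make_yield_phantom(m, targets)
  tb <- report_as_table(evaluate_reconstruction(xt, xt, targets, m, g),
                        method = "nasols")
  expect_identical(names(tb)[1:8],
                   c("method", "target", "rec_x", "rec_y", "rec_z", "le",
                     "nrmse", "cnr"))
})
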