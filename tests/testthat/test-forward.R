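props_h <- optical_properties(0.01, 1.0, 1.0)

test_that("optical properties are validated", {
  expect_error(optical_properties(-0.1, 1), "mua")
  expect_error(optical_properties(0.1, 0), "musp")
  expect_error(optical_properties(0.1, 1, 0.9), "n_refr")
  expect_equal(nasols:::.robin_An(1), 1)
  expect_gt(nasols:::.robin_An(1.37), 1)
})

test_that("assembled FEM system is symmetric positive definite", {
  sys <- assemble_diffusion_system(single_tet_mesh(), props_h)
  K <- as.matrix(sys$K)
  expect_equal(K, t(K), tolerance = 1e-14)
  expect_true(all(eigen(K, symmetric = TRUE, only.values = TRUE)$values > 0))

  m <- generate_cube_mesh(10, 5)
  K2 <- as.matrix(assemble_diffusion_system(m, props_h)$K)
  expect_lt(max(abs(K2 - t(K2))) / max(abs(K2)), 1e-12)
  expect_true(all(eigen(K2, symmetric = TRUE, only.values = TRUE)$values > 0))
})

test_that("doubling the absorption raises every diagonal entry", {
  m <- generate_cube_mesh(10, 5)
  # hold D and the boundary term fixed so only the mass term moves
  base <- optical_properties(0.01, 1.0, 1.0)
  diag1 <- Matrix::diag(assemble_diffusion_system(m, base)$K)
  dbl <- optical_properties(0.02, 1.0 + 0.01 - 0.02, 1.0) # same mua + musp
  diag2 <- Matrix::diag(assemble_diffusion_system(m, dbl)$K)
  expect_true(all(diag2 > diag1))
})

test_that("missing region properties raise a configuration error", {
  m <- single_tet_mesh()
  m$region <- 7L
  expect_error(assemble_diffusion_system(m, list(`1` = props_h)),
               "region label")
})

test_that("fluence matches the infinite-medium Green's function", {
  m <- generate_cube_mesh(25, 2.5)
  sys <- assemble_diffusion_system(m, props_h)
  ctr <- c(12.5, 12.5, 12.5)
  src <- which.min(colSums((t(m$nodes) - ctr)^2))
  b <- numeric(n_nodes(m)); b[src] <- 1
  phi <- solve_diffusion(sys, b)
  r <- sqrt(colSums((t(m$nodes) - ctr)^2))
  sel <- r >= 4 & r <= 8
  relerr <- abs(phi[sel] - greens_infinite(r[sel], props_h)) /
    greens_infinite(r[sel], props_h)
  expect_lt(max(relerr), 0.2)
})

test_that("fluence decays monotonically along a radial chain", {
  m <- generate_cube_mesh(25, 2.5)
  sys <- assemble_diffusion_system(m, props_h)
  b <- numeric(n_nodes(m))
  ctr_id <- which.min(colSums((t(m$nodes) - 12.5)^2))
  b[ctr_id] <- 1
  phi <- solve_diffusion(sys, b)
  chain <- which(m$nodes[, 2] == 12.5 & m$nodes[, 3] == 12.5 &
                   m$nodes[, 1] >= 12.5)
  chain <- chain[order(m$nodes[chain, 1])]
  expect_true(all(diff(phi[chain]) < 0))
})

test_that("point sources sit one transport mean free path under the anchor", {
  m <- generate_cube_mesh(25, 2.5)
  p <- boundary_patch(m)
  src <- place_point_source(m, p, c(25, 12.5, 12.5), musp = 1.0)
  expect_equal(src$spec$interior_position, c(24, 12.5, 12.5),
               tolerance = 1e-12)
  expect_equal(sum(src$load), 1, tolerance = 1e-12)

  # depth reaching a mesh node concentrates the load on that node
  src2 <- place_point_source(m, p, c(25, 12.5, 12.5), musp = 1 / 2.5)
  expect_equal(sum(src2$load), 1, tolerance = 1e-12)
  node <- which.min(colSums((t(m$nodes) - c(22.5, 12.5, 12.5))^2))
  expect_equal(as.numeric(src2$load[node]), 1, tolerance = 1e-9)
})

test_that("field-of-view detector selection obeys the angular window", {
  m <- generate_cube_mesh(25, 2.5)
  p <- boundary_patch(m)
  src <- place_point_source(m, p, c(25, 12.5, 12.5), musp = 1.0)

  all_det <- select_detectors_fov(m, p, src, fov_deg = 360)
  expect_setequal(as.integer(all_det), p$boundary_nodes)

  det <- select_detectors_fov(m, p, src, fov_deg = 120)
  ctr <- colMeans(m$nodes)
  ang <- atan2(m$nodes[det, 2] - ctr[2], m$nodes[det, 1] - ctr[1])
  dev <- abs(atan2(sin(ang - pi), cos(ang - pi))) * 180 / pi
  expect_true(all(dev <= 60 + 1e-9))
  # the node diametrically opposite the source is included
  opp <- which.min(colSums((t(m$nodes) - c(0, 12.5, 12.5))^2))
  expect_true(opp %in% det)
  # a node at ~100 deg from the source direction is excluded
  side <- which.min(colSums((t(m$nodes) - c(10, 25, 12.5))^2))
  expect_false(side %in% det)

  expect_error(select_detectors_fov(m, p, src, fov_deg = 0), "fov")
})

test_that("detector sets of opposite sources are 180-degree mirrors", {
  m <- generate_cube_mesh(25, 2.5)
  p <- boundary_patch(m)
  anchors <- layout_projections(m, p, 8)
  srcs <- lapply(seq_len(8), function(k)
    place_point_source(m, p, anchors[k, ], musp = 1.0))
  dets <- lapply(srcs, function(s) select_detectors_fov(m, p, s, 120))
  rot180 <- function(pos) cbind(25 - pos[, 1], 25 - pos[, 2], pos[, 3])
  for (k in 1:4) {
    a <- m$nodes[as.integer(dets[[k]]), , drop = FALSE]
    b <- m$nodes[as.integer(dets[[k + 4]]), , drop = FALSE]
    key <- function(x) sort(apply(round(x, 9), 1, paste, collapse = ","))
    expect_identical(key(rot180(a)), key(b))
  }
})

test_that("system matrix rows couple excitation and emission solves", {
  m <- generate_cube_mesh(25, 5)
  p <- boundary_patch(m)
  anchors <- layout_projections(m, p, 2)
  srcs <- lapply(1:2, function(k)
    place_point_source(m, p, anchors[k, ], musp = 1.0))
  dets <- lapply(srcs, function(s)
    select_detectors_fov(m, p, s, 120, max_detectors = 8))
  sm <- build_system_matrix(m, props_h, props_h, srcs, dets)
  expect_true(all(is.finite(sm$A)))
  expect_true(all(sm$A >= 0))
  expect_equal(nrow(sm$A), sum(lengths(dets)))
  expect_equal(ncol(sm$A), n_nodes(m))
  expect_equal(sm$row_index$source, rep(1:2, times = lengths(dets)))

  born <- build_system_matrix(m, props_h, props_h, srcs, dets,
                              normalize = "born")
  keep <- unlist(born$kept_mask)
  expect_true(all(born$row_index$row_scale > 0))
  expect_equal(born$A * born$row_index$row_scale,
               sm$A[keep, , drop = FALSE], tolerance = 1e-12)
})

test_that("Green's-function factors satisfy reciprocity", {
  m <- generate_cube_mesh(25, 5)
  sys <- assemble_diffusion_system(m, props_h)
  a <- 30L; b <- 100L
  ea <- numeric(n_nodes(m)); ea[a] <- 1
  eb <- numeric(n_nodes(m)); eb[b] <- 1
  expect_equal(solve_diffusion(sys, ea)[b], solve_diffusion(sys, eb)[a],
               tolerance = 1e-10)
})
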