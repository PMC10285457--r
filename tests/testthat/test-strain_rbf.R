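# direct re-summation oracle for the kernel expansion
rbf_sum_oracle <- function(src, gamma, beta, tg) {
  vapply(seq_len(nrow(tg)), function(q) {
    r <- sqrt((tg[q, 1] - src[, 1])^2 + (tg[q, 2] - src[, 2])^2)
    sum(gamma * r^3) + beta[1] + beta[2] * tg[q, 1] + beta[3] * tg[q, 2]
  }, numeric(1))
}

random_sources <- function(n, seed) {
  set.seed(seed)
  cbind(runif(n, 0, 20), runif(n, 0, 20))
}

test_that("constant and affine fields are absorbed by the polynomial", {
  src <- random_sources(25, 1)
  m <- fit_rbf(src, cbind(rep(0.5, 25), rep(-0.3, 25)))
  expect_lt(max(abs(m$gamma)), 1e-10)
  expect_equal(m$beta[, 1], c(0.5, 0, 0), tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(m$beta[, 2], c(-0.3, 0, 0), tolerance = 1e-10, ignore_attr = TRUE)
  aff <- cbind(0.01 * src[, 1] + 0.002 * src[, 2], 0.004 * src[, 2])
  ma <- fit_rbf(src, aff)
  tg <- random_sources(9, 2)
  expect_equal(eval_displacement(ma, tg),
               cbind(0.01 * tg[, 1] + 0.002 * tg[, 2], 0.004 * tg[, 2]),
               tolerance = 1e-9, ignore_attr = TRUE)
  gr <- eval_gradient(ma, tg)
  expect_equal(gr, matrix(rep(c(0.01, 0.002, 0, 0.004), each = 9), 9, 4),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("fitting reproduces known coefficients and honors the constraints", {
  src <- random_sources(20, 3)
  set.seed(4)
  gam <- cbind(rnorm(20, 0, 1e-3), rnorm(20, 0, 1e-3))
  # project onto the orthogonality space so the synthetic field is canonical
  P <- cbind(1, src)
  gam <- gam - P %*% solve(crossprod(P), crossprod(P, gam))
  beta <- cbind(c(0.1, 0.01, -0.02), c(-0.2, 0.005, 0.03))
  g <- cbind(rbf_sum_oracle(src, gam[, 1], beta[, 1], src),
             rbf_sum_oracle(src, gam[, 2], beta[, 2], src))
  m <- fit_rbf(src, g)
  expect_equal(m$gamma, gam, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(m$beta, beta, tolerance = 1e-6, ignore_attr = TRUE)
  # orthogonality side conditions hold for any fit
  expect_lt(max(abs(crossprod(P, m$gamma))), 1e-8)
  # exact interpolation at the sources
  expect_lt(max(abs(eval_displacement(m, src) - g)), 1e-8)
  # independent re-summation at a fresh target
  tg <- random_sources(6, 5)
  expect_equal(eval_displacement(m, tg)[, 1],
               rbf_sum_oracle(src, m$gamma[, 1], m$beta[, 1], tg),
               tolerance = 1e-12)
})

test_that("degenerate source configurations are handled", {
  src <- random_sources(12, 6)
  g <- cbind(src[, 1] * 0.01, src[, 2] * 0.01)
  dup <- rbind(src, src[1, ] + c(1e-8, 0))
  expect_message(m <- fit_rbf(dup, rbind(g, g[1, ])), "duplicate")
  expect_equal(nrow(m$sources), 12)
  coll <- cbind(seq_len(10), 2 * seq_len(10) + 1)
  expect_error(fit_rbf(coll, coll * 0.01), "collinear")
  expect_error(fit_rbf(src[1:2, ], g[1:2, ]), "at least 3")
})

test_that("analytic gradients agree with central finite differences", {
  src <- random_sources(40, 7)
  set.seed(8)
  g <- cbind(rnorm(40, 0, 0.1), rnorm(40, 0, 0.1))
  m <- fit_rbf(src, g)
  tg <- random_sources(10, 9)
  gr <- eval_gradient(m, tg)
  h <- 1e-4
  fd <- cbind(
    (eval_displacement(m, cbind(tg[, 1] + h, tg[, 2]))[, 1] -
       eval_displacement(m, cbind(tg[, 1] - h, tg[, 2]))[, 1]) / (2 * h),
    (eval_displacement(m, cbind(tg[, 1], tg[, 2] + h))[, 1] -
       eval_displacement(m, cbind(tg[, 1], tg[, 2] - h))[, 1]) / (2 * h),
    (eval_displacement(m, cbind(tg[, 1] + h, tg[, 2]))[, 2] -
       eval_displacement(m, cbind(tg[, 1] - h, tg[, 2]))[, 2]) / (2 * h),
    (eval_displacement(m, cbind(tg[, 1], tg[, 2] + h))[, 2] -
       eval_displacement(m, cbind(tg[, 1], tg[, 2] - h))[, 2]) / (2 * h))
  expect_lt(max(abs(gr - fd) / pmax(abs(fd), 1e-6)), 1e-5)
  # kernel derivative vanishes at a target coinciding with a source
  gr_at_src <- eval_gradient(m, src)
  expect_true(all(is.finite(gr_at_src)))
})

test_that("the incompressible annulus field gives the closed-form gradient", {
  rings <- as.matrix(expand.grid(r = seq(9, 12, 0.25),
                                 a = seq(0, 2 * pi, length.out = 121)[-121]))
  src <- cbind(rings[, "r"] * cos(rings[, "a"]), rings[, "r"] * sin(rings[, "a"]))
  fld <- annulus_field(a = 0.5, center = c(0, 0))
  m <- fit_rbf(src, fld(src))
  gr <- eval_gradient(m, cbind(10, 0))
  expect_equal(unname(gr[1, "duxdx"]), -0.005, tolerance = 2e-4)
  expect_equal(unname(gr[1, "duydy"]), +0.005, tolerance = 2e-4)
  eps <- strain_cartesian(gr)
  expect_equal(as.vector(eps), c(-0.005, 0.005, 0), tolerance = 2e-4)
})

test_that("Cartesian strain handles rigid and shear modes", {
  # infinitesimal rigid rotation: antisymmetric gradient, zero strain
  w <- 0.01
  expect_equal(as.vector(strain_cartesian(c(0, -w, w, 0))), c(0, 0, 0))
  # simple shear u_x = c y
  expect_equal(as.vector(strain_cartesian(c(0, 0.03, 0, 0))), c(0, 0, 0.03))
})

test_that("polar rotation satisfies the tensor identities", {
  expect_equal(as.vector(rotate_to_polar(c(0.01, -0.02, 0.03), 0)),
               c(0.01, -0.02, 0.03))
  expect_equal(as.vector(rotate_to_polar(c(-0.005, 0.005, 0), pi / 2)),
               c(0.005, -0.005, 0), tolerance = 1e-12)
  expect_equal(as.vector(rotate_to_polar(c(0, 0, 0.04), pi / 4)),
               c(0.02, -0.02, 0), tolerance = 1e-12)
  set.seed(10)
  eps <- matrix(rnorm(60, 0, 0.05), 20, 3)
  th <- runif(20, -pi, pi)
  rot <- rotate_to_polar(eps, th)
  expect_lt(max(abs((rot[, 1] + rot[, 2]) - (eps[, 1] + eps[, 2]))), 1e-12)
  back <- rotate_to_polar(rot, -th)
  expect_equal(back, eps, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("strain maps vanish for rigid motion and at the reference frame", {
  grid <- build_wall_grid(circle_contour(8, c(15, 15), 48), n_points = 24)
  nodes <- wallstrain:::grid_node_matrix(grid)
  K <- 5
  pos <- array(NA_real_, c(nrow(nodes), K, 2))
  w <- 1e-3  # translation + infinitesimal rotation about the center
  for (k in seq_len(K)) {
    s <- (k - 1) / (K - 1)
    rel <- sweep(nodes, 2, c(15, 15))
    pos[, k, ] <- nodes + s * cbind(0.4 - w * rel[, 2], -0.7 + w * rel[, 1])
  }
  sf <- map_strains(track_from_positions(pos), grid)
  expect_equal(max(abs(sf$fields[[1]])), 0)
  for (k in 2:K) expect_lt(max(abs(sf$fields[[k]][, 1:6])), 1e-6)
})

test_that("the annulus inflation strain is recovered from true motion", {
  grid <- build_wall_grid(circle_contour(10, c(20, 20)))  # auto density
  mot <- analytic_inflation_motion(grid, 0.5, 9)
  nodes <- wallstrain:::grid_node_matrix(grid)
  K <- 9
  pos <- array(NA_real_, c(nrow(nodes), K, 2))
  for (k in seq_len(K)) pos[, k, ] <- nodes + mot$disp[, k, ]
  sf <- map_strains(track_from_positions(pos), grid)
  pk <- which.max(mot$A)
  inner <- seq_len(grid$n_points)
  truth <- mot$strain_polar(nodes[inner, ], pk)
  est <- sf$fields[[pk]][inner, "eps_circ"]
  expect_lt(max(abs(est - truth[, "eps_circ"]) / truth[, "eps_circ"]), 0.05)
  # the radial derivative spans only the 4 layers of the 2 mm wall, so its
  # recovery is a little looser than the circumferential one
  est_rad <- sf$fields[[pk]][inner, "eps_rad"]
  expect_lt(max(abs(est_rad - truth[, "eps_rad"]) / abs(truth[, "eps_rad"])), 0.1)
})

test_that("strain tables have the documented long format", {
  grid <- build_wall_grid(circle_contour(6, c(10, 10), 36), n_points = 16, n_layers = 3)
  nodes <- wallstrain:::grid_node_matrix(grid)
  pos <- array(NA_real_, c(nrow(nodes), 2, 2))
  pos[, 1, ] <- nodes
  pos[, 2, ] <- nodes
  sf <- map_strains(track_from_positions(pos), grid)
  tab <- strain_table(sf)
  expect_named(tab, c("frame", "layer", "index", "eps_circ", "eps_rad",
                      "eps_shear", "eps_x", "eps_y", "gamma_xy"))
  expect_equal(nrow(tab), 2 * 48)
})
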