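test_that("backscatter mapping follows the amplitude power law", {
  expect_equal(bsc_from_intensity(255), 1.0)
  expect_equal(bsc_from_intensity(0), 0.0)
  expect_equal(bsc_from_intensity(128), 0.8712, tolerance = 1e-4)
  expect_message(b <- bsc_from_intensity(c(-5, 300)), "clamping")
  expect_equal(b, c(0, 1))
  # monotone in intensity
  expect_true(all(diff(bsc_from_intensity(0:255)) > 0))
})

test_that("the phantom template has the expected tissue contrast", {
  tmpl <- make_phantom_template(lumen_radius = 8, seed = 5)
  nr <- nrow(tmpl$img); nc <- ncol(tmpl$img)
  px <- rep((seq_len(nc) - 1) * 0.22, each = nr)
  py <- rep((seq_len(nr) - 1) * 0.22, nc)
  r <- sqrt((px - tmpl$center[1])^2 + (py - tmpl$center[2])^2)
  wall <- r >= tmpl$r_inner & r <= tmpl$r_outer
  lumen <- r < tmpl$r_inner - 0.5
  backg <- r > tmpl$r_outer + 0.5 & py < tmpl$center[2]
  expect_gt(mean(tmpl$img[wall]), mean(tmpl$img[backg]))
  expect_gt(mean(tmpl$img[backg]), mean(tmpl$img[lumen]))
  # grid inner layer sits on the lumen-wall interface
  ri <- sqrt((tmpl$grid$nodes[1, , 1] - tmpl$center[1])^2 +
               (tmpl$grid$nodes[1, , 2] - tmpl$center[2])^2)
  expect_lt(max(abs(ri - tmpl$r_inner)), 0.22)
  # deterministic under a fixed seed
  expect_identical(tmpl$img, make_phantom_template(lumen_radius = 8, seed = 5)$img)
  expect_error(make_phantom_template(lumen_radius = 30), "does not fit")
})

test_that("the masked sector darkens the wall locally", {
  tmpl <- make_phantom_template(lumen_radius = 8, seed = 5,
                                mask_sector = list(center_deg = 0, width_deg = 60))
  nr <- nrow(tmpl$img); nc <- ncol(tmpl$img)
  px <- rep((seq_len(nc) - 1) * 0.22, each = nr)
  py <- rep((seq_len(nr) - 1) * 0.22, nc)
  dx <- px - tmpl$center[1]; dy <- py - tmpl$center[2]
  r <- sqrt(dx^2 + dy^2)
  wall <- r >= tmpl$r_inner & r <= tmpl$r_outer
  ang <- atan2(dy, dx) * 180 / pi
  expect_lt(mean(tmpl$img[wall & abs(ang) < 25]),
            mean(tmpl$img[wall & abs(ang) > 45]) - 80)
})

test_that("the inflation profile is zero at the ends and peaks mid-cycle", {
  grid <- build_wall_grid(circle_contour(10, c(20, 20)), n_points = 48)
  mot <- analytic_inflation_motion(grid, 0.5, 33)
  expect_equal(mot$A[1], 0)
  expect_equal(mot$A[33], 0)
  expect_equal(which.max(mot$A), 17)
  expect_equal(max(mot$A), 0.5)
  # inner node displacement at the peak equals the peak amplitude
  inner_disp <- sqrt(mot$disp[seq_len(48), 17, 1]^2 + mot$disp[seq_len(48), 17, 2]^2)
  expect_equal(inner_disp, rep(0.5, 48), tolerance = 1e-6, ignore_attr = TRUE)
  # closed-form circumferential strain at the inner wall: A r_in / r^2
  st <- mot$strain_polar(cbind(30, 20), 17)
  expect_equal(unname(st[1, "eps_circ"]), 0.05, tolerance = 1e-3)
  expect_equal(unname(st[1, "eps_rad"]), -0.05, tolerance = 1e-3)
})

test_that("the simulator is seeded-deterministic and motion-faithful", {
  sim <- small_sim()
  tmpl <- sim$template
  # bit-identical re-simulation under the same seed
  mot <- analytic_inflation_motion(tmpl$grid, 0.5, 17)
  sim2 <- simulate_bmode(tmpl, mot, n_scatterers = 8000, seed = 3)
  expect_identical(sim$seq$frames, sim2$seq$frames)
  # zero motion: all frames identical
  mot0 <- analytic_inflation_motion(tmpl$grid, 0, 4)
  sim0 <- simulate_bmode(tmpl, mot0, n_scatterers = 3000, seed = 2)
  for (k in 2:4) expect_identical(sim0$seq$frames[, , k], sim0$seq$frames[, , 1])
  # wall patch moves with the imposed field: integer cross-correlation peak
  pk <- which.max(mot$A)
  cx_px <- tmpl$center[1] / 0.22; cy_px <- tmpl$center[2] / 0.22
  rows <- round(cy_px) + (-4:4)
  cols <- round(cx_px - (tmpl$r_inner + 1) / 0.22) + (-4:4)
  patch1 <- sim$seq$frames[rows, cols, 1]
  imposed_px <- -mot$A[pk] * tmpl$r_inner / (tmpl$r_inner + 1) / 0.22
  ssd <- vapply(-4:0, function(s) {
    sum((sim$seq$frames[rows, cols + s, pk] - patch1)^2)
  }, numeric(1))
  best <- (-4:0)[which.min(ssd)]
  expect_lt(abs(best - imposed_px), 1)
})

test_that("scatterer maps respect the ROI and the transition zone", {
  sim <- small_sim()
  tmpl <- sim$template
  sc <- sim$scatterers
  r <- sqrt((sc$x_mm - tmpl$center[1])^2 + (sc$y_mm - tmpl$center[2])^2)
  expect_true(all(r[sc$coherent] >= tmpl$r_inner - 1e-9))
  expect_true(all(r[sc$coherent] <= tmpl$r_outer + 1e-9))
  inc <- !sc$coherent
  expect_true(all(r[inc] <= tmpl$r_inner - 1 | r[inc] >= tmpl$r_outer + 1))
  expect_true(all(sc$bsc >= 0 & sc$bsc <= 1))
  expect_error(simulate_bmode(tmpl, sim$truth, n_scatterers = 50), "at least 100")
})

test_that("fully developed background speckle is Rayleigh-distributed", {
  tmpl <- make_phantom_template(seed = 7)
  mot <- analytic_inflation_motion(tmpl$grid, 0.5, 3)
  sim <- simulate_bmode(tmpl, mot, n_scatterers = 11000, seed = 7)
  env <- sim$envelope1
  nr <- nrow(env); nc <- ncol(env)
  px <- rep((seq_len(nc) - 1) * 0.22, each = nr)
  py <- rep((seq_len(nr) - 1) * 0.22, nc)
  r <- sqrt((px - tmpl$center[1])^2 + (py - tmpl$center[2])^2)
  bg <- r > tmpl$r_outer + 3 & py < tmpl$center[2] + tmpl$r_outer
  snr <- mean(env[bg]) / sd(env[bg])
  expect_gt(snr, 1.91 - 0.15)
  expect_lt(snr, 1.91 + 0.15)
})
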