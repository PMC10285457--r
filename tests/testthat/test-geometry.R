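test_that("contour construction validates input and normalizes orientation", {
  expect_error(wall_contour(cbind(c(0, 1), c(0, 1))), "at least 3")
  # consecutive duplicates are dropped, closing repeat tolerated
  c1 <- wall_contour(rbind(c(0, 0), c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0)))
  expect_equal(nrow(c1$points), 4)
  # clockwise input is reversed to positive signed area
  cw <- cbind(c(0, 0, 1, 1), c(0, 1, 1, 0))
  expect_gt(wallstrain:::contour_area(wall_contour(cw)$points), 0)
})

test_that("resampling gives equal arc spacing rooted at the posterior point", {
  rc <- resample_contour(circle_contour(10, c(20, 20), 8), 8)
  d <- sqrt(rowSums((rc$points[c(2:8, 1), ] - rc$points)^2))
  # equal chords on a symmetric figure; arc spacing close to the circle arc
  expect_lt(diff(range(d)), 1e-3)
  arc <- wallstrain:::contour_perimeter(
    resample_contour(circle_contour(10, c(20, 20), 8), 512)$points) / 8
  expect_equal(arc, 2 * pi * 10 / 8, tolerance = 0.01)
  # generic landmark cloud: arc spacings equal within 0.1% of the mean,
  # measured along a dense subdivision of the same curve
  set.seed(5)
  lm <- circle_contour(10, c(20, 20), 10)$points +
    matrix(rnorm(20, 0, 0.4), 10, 2)
  rc2 <- resample_contour(lm, 40)
  dense <- resample_contour(lm, 4000)$points
  seg <- sqrt(rowSums((dense[c(2:4000, 1), ] - dense)^2))
  arcs <- vapply(seq_len(40), function(k)
    sum(seg[((k - 1) * 100 + 1):(k * 100)]), numeric(1))
  expect_lt(diff(range(arcs)) / mean(arcs), 1e-3)
  # the 40-point nodes lie on the dense curve at multiples of total/40
  expect_equal(rc2$points, dense[seq(1, 4000, 100), ], tolerance = 1e-3,
               ignore_attr = TRUE)
  # node 1 is the most posterior point (max y)
  expect_equal(which.max(rc2$points[, 2]), 1)
  expect_error(resample_contour(cbind(c(0, 1), c(0, 1)), 10), "at least 3")
})

test_that("resampling is translation-equivariant", {
  lm <- circle_contour(10, c(20, 20), 12)$points
  a <- resample_contour(lm, 24)$points
  b <- resample_contour(sweep(lm, 2, c(3.5, -1.25), "+"), 24)$points
  expect_equal(sweep(a, 2, c(3.5, -1.25), "+"), b, tolerance = 1e-9)
})

test_that("wall grid projects the circle outward radially with even layers", {
  g <- build_wall_grid(circle_contour(10, c(20, 20)), thickness = 2, n_layers = 4)
  expect_equal(g$n_points, 94)  # perimeter / (thickness/3), nearest even
  r <- sqrt((g$nodes[, , 1] - 20)^2 + (g$nodes[, , 2] - 20)^2)
  expect_equal(rowMeans(r), c(10, 10 + 2 / 3, 10 + 4 / 3, 12), tolerance = 1e-3)
  expect_lt(max(abs(r[4, ] - 12)), 0.01)
  # matched inner/outer nodes sit thickness apart on a circle
  d <- sqrt((g$nodes[4, , 1] - g$nodes[1, , 1])^2 +
              (g$nodes[4, , 2] - g$nodes[1, , 2])^2)
  expect_lt(max(abs(d - 2)), 0.02)
  # equal arc spacings within every layer (1%)
  for (l in 1:4) {
    p <- g$nodes[l, , ]
    sp <- sqrt(rowSums((p[c(2:94, 1), ] - p)^2))
    expect_lt(diff(range(sp)) / mean(sp), 0.01)
  }
  # element aspect ratio (circumferential / radial spacing) near 1
  for (l in 1:4) {
    p <- g$nodes[l, , ]
    sp <- mean(sqrt(rowSums((p[c(2:94, 1), ] - p)^2)))
    expect_gt(sp / (2 / 3), 0.8)
    expect_lt(sp / (2 / 3), 1.25)
  }
})

test_that("grid construction is translation-equivariant", {
  inner <- circle_contour(8, c(15, 15), 48)
  g1 <- build_wall_grid(inner, n_points = 40)
  shifted <- wall_contour(sweep(inner$points, 2, c(2, 7), "+"))
  g2 <- build_wall_grid(shifted, n_points = 40)
  expect_equal(g1$nodes[, , 1] + 2, g2$nodes[, , 1], tolerance = 1e-9)
  expect_equal(g1$nodes[, , 2] + 7, g2$nodes[, , 2], tolerance = 1e-9)
  expect_equal(g1$theta, g2$theta, tolerance = 1e-9)
})

test_that("tangent angles follow the circle geometry", {
  g <- build_wall_grid(circle_contour(10, c(20, 20)), n_points = 96)
  p <- g$nodes[1, , ]
  # node on the horizontal through the center: vertical tangent
  i_right <- which.min((p[, 1] - 30)^2 + (p[, 2] - 20)^2)
  expect_lt(abs(abs(g$theta[1, i_right]) - pi / 2), 0.02)
  # topmost node (min y in image coordinates): horizontal tangent
  i_top <- which.min(p[, 2])
  expect_lt(abs(g$theta[1, i_top]), 0.02)
  expect_true(all(g$theta > -pi & g$theta <= pi))
})

test_that("grid table export has the documented layout", {
  g <- build_wall_grid(circle_contour(6, c(10, 10), 36), n_points = 20, n_layers = 3)
  df <- as.data.frame(g)
  expect_named(df, c("layer", "index", "x_mm", "y_mm", "theta_rad"))
  expect_equal(nrow(df), 60)
  expect_equal(df$x_mm[df$layer == 2], g$nodes[2, , 1])
})

test_that("ROI mask covers the wall ring only", {
  g <- build_wall_grid(circle_contour(6, c(10, 10), 48), n_points = 40)
  m <- roi_mask(g, c(91, 91), c(0.22, 0.22))
  px <- rep((seq_len(91) - 1) * 0.22, each = 91)
  py <- rep((seq_len(91) - 1) * 0.22, 91)
  r <- matrix(sqrt((px - 10)^2 + (py - 10)^2), 91, 91)
  expect_true(all(r[m] > 5.8 & r[m] < 8.2))
  expect_true(all(!m[r < 5.8]))
  expect_true(all(!m[r > 8.2]))
})
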