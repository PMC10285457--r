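# Shared fixtures, built in code. Heavy simulations are cached for the test
# run so several files can reuse them.

circle_contour <- function(r = 10, center = c(20, 20), n = 72) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  wall_contour(cbind(center[1] + r * cos(th), center[2] + r * sin(th)))
}

# radial annulus field u = (a / r) r_hat about `center`
annulus_field <- function(a = 0.5, center = c(0, 0)) {
  function(p) {
    p <- as.matrix(p)
    dxy <- sweep(p, 2, center)
    r2 <- pmax(rowSums(dxy^2), 1e-18)
    (a / r2) * dxy
  }
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small pulsating phantom (reduced radius/frames/scatterers for test speed)
small_sim <- function() {
  cached("small_sim", {
    tmpl <- make_phantom_template(lumen_radius = 8, seed = 3)
    mot <- analytic_inflation_motion(tmpl$grid, 0.5, 17)
    simulate_bmode(tmpl, mot, n_scatterers = 8000, seed = 3)
  })
}

# synthetic track_result from an explicit positions array (mm)
track_from_positions <- function(pos, frames = seq_len(dim(pos)[2]),
                                 direction = "merged") {
  disp <- pos
  for (j in 1:2) disp[, , j] <- pos[, , j] - pos[, 1, j]
  structure(list(positions = pos, displacements = disp, frames = frames,
                 direction = direction),
            class = "track_result")
}

# smooth speckle-like test image (blurred white noise, 0..255)
speckle_image <- function(nr = 120, nc = 120, seed = 42) {
  set.seed(seed)
  img <- matrix(runif(nr * nc), nr, nc)
  img <- wallstrain:::cpp_gauss_blur(img, 1.2)
  img <- img - min(img)
  img / max(img) * 255
}
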