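#' Backscatter coefficient from template pixel amplitude
#'
#' `BSC = (I/255)^gamma`, the empirical mapping from template image
#' brightness to scatterer echo strength; `gamma` defaults to 0.2 and
#' `0^gamma` is 0. Out-of-range amplitudes are clamped with a message.
#'
#' @param intensity pixel amplitudes in 0..255 (vectorized).
#' @param gamma compression exponent.
#' @return backscatter coefficients in 0..1.
#' @export
bsc_from_intensity <- function(intensity, gamma = 0.2) {
  if (any(intensity < 0 | intensity > 255)) {
    message("bsc_from_intensity: clamping amplitudes to [0, 255]")
    intensity <- pmin(pmax(intensity, 0), 255)
  }
  (intensity / 255)^gamma
}

#' Synthetic B-mode template of an annular vessel wall
#'
#' Builds an 8-bit template image emulating a transverse AAA scan: a dark
#' lumen (I ~ 10) inside a bright annular wall (I ~ 180) of the given
#' thickness, a mid-gray speckled background (I ~ 80), and a bright flat
#' "spine" band below the annulus. A wall grid is built on the lumen-wall
#' interface. Optionally a low-echo angular sector can be carved out of the
#' wall (`mask_sector`) to emulate the signal void of lateral walls.
#'
#' @param lumen_radius inner-wall radius, mm.
#' @param thickness wall thickness, mm.
#' @param image_size_mm image extent `c(width, height)`, mm.
#' @param pixel_spacing `c(dx, dy)`, mm/px.
#' @param n_layers grid layers.
#' @param mask_sector `NULL`, or `list(center_deg =, width_deg =)` giving the
#'   angular sector (degrees, 0 = to the right of the center, measured
#'   toward +y/posterior) where the wall is rendered at background level.
#' @param seed RNG seed for the background texture.
#' @return object of class `phantom_template`: list with `img` (matrix,
#'   0..255), `grid` ([build_wall_grid()]), `pixel_spacing`, `center`,
#'   `r_inner`, `r_outer`.
#' @export
make_phantom_template <- function(lumen_radius = 10, thickness = 2,
                                  image_size_mm = c(40, 40),
                                  pixel_spacing = c(0.22, 0.22),
                                  n_layers = 4L, mask_sector = NULL,
                                  seed = 1L) {
  nc <- as.integer(round(image_size_mm[1] / pixel_spacing[1]))
  nr <- as.integer(round(image_size_mm[2] / pixel_spacing[2]))
  cx <- image_size_mm[1] / 2
  cy <- 0.45 * image_size_mm[2]
  r_out <- lumen_radius + thickness
  if (cx - r_out < 0 || cy - r_out < 0 || cy + r_out > image_size_mm[2])
    stop("wall does not fit inside the image")
  set.seed(seed)
  px <- rep((seq_len(nc) - 1) * pixel_spacing[1], each = nr)
  py <- rep((seq_len(nr) - 1) * pixel_spacing[2], nc)
  r <- sqrt((px - cx)^2 + (py - cy)^2)
  img <- 80 + rnorm(nr * nc, 0, 20)               # speckled background
  lum <- r < lumen_radius
  img[lum] <- 10 + abs(rnorm(sum(lum), 0, 4))     # dark lumen
  wall <- r >= lumen_radius & r <= r_out
  img[wall] <- 180 + rnorm(sum(wall), 0, 10)      # bright wall
  spine <- py >= cy + r_out + 2 & py <= cy + r_out + 5
  img[spine] <- 200 + rnorm(sum(spine), 0, 10)    # spine interface band
  if (!is.null(mask_sector)) {
    ang <- atan2(py - cy, px - cx) * 180 / pi
    dang <- ((ang - mask_sector$center_deg + 180) %% 360) - 180
    void <- wall & abs(dang) <= mask_sector$width_deg / 2
    img[void] <- 35 + rnorm(sum(void), 0, 5)      # lateral signal void
  }
  img <- matrix(pmin(pmax(img, 0), 255), nr, nc)
  circ <- cbind(cx + lumen_radius * cos(seq(0, 2 * pi, length.out = 73)[-73]),
                cy + lumen_radius * sin(seq(0, 2 * pi, length.out = 73)[-73]))
  grid <- build_wall_grid(wall_contour(circ), thickness = thickness,
                          n_layers = n_layers)
  structure(list(img = img, grid = grid, pixel_spacing = pixel_spacing,
                 center = c(cx, cy), r_inner = lumen_radius, r_outer = r_out,
                 image_size_mm = image_size_mm, seed = seed),
            class = "phantom_template")
}

#' Analytic inflation/deflation ground-truth motion
#'
#' Incompressible plane-strain inflation kinematics of an annulus: radial
#' displacement `u_r(r, t) = A(t) * r_inner / r`, with the amplitude
#' following a smooth systole/diastole profile
#' `A(t) = peak * sin^2(pi k / (K - 1))` over the cycle (zero at both ends,
#' single peak at mid-cycle). The closed-form strains
#' `eps_circ = A * r_inner / r^2`, `eps_rad = -A * r_inner / r^2` serve as
#' the strain oracle.
#'
#' @param grid a `wall_grid` (annular).
#' @param peak_inner_displacement peak radial displacement of the inner
#'   wall, mm.
#' @param n_frames frames per cycle.
#' @param center annulus center, mm; default the inner-contour centroid.
#' @return object of class `ground_truth_motion`: `disp` (`m x K x 2` node
#'   displacements, layer-major), `A` (amplitude per frame), `field(points,
#'   frame)` displacement closure, `strain_polar(points, frame)` closed-form
#'   (eps_circ, eps_rad) closure, `center`, `r_inner`.
#' @export
analytic_inflation_motion <- function(grid, peak_inner_displacement = 0.5,
                                      n_frames = 33L, center = NULL) {
  stopifnot(inherits(grid, "wall_grid"), n_frames >= 3)
  if (is.null(center)) center <- contour_centroid(grid$inner$points)
  r_inner <- mean(sqrt(rowSums(sweep(grid$inner$points, 2, center)^2)))
  K <- as.integer(n_frames)
  A <- peak_inner_displacement * sin(pi * (seq_len(K) - 1) / (K - 1))^2
  field <- function(points, frame) {
    p <- as.matrix(points)
    dxy <- sweep(p, 2, center)
    r <- pmax(sqrt(rowSums(dxy^2)), 1e-9)
    (A[frame] * r_inner / r^2) * dxy
  }
  strain_polar <- function(points, frame) {
    p <- as.matrix(points)
    r <- pmax(sqrt(rowSums(sweep(p, 2, center)^2)), 1e-9)
    e <- A[frame] * r_inner / r^2
    cbind(eps_circ = e, eps_rad = -e)
  }
  nodes <- grid_node_matrix(grid)
  disp <- array(NA_real_, c(nrow(nodes), K, 2))
  for (k in seq_len(K)) disp[, k, ] <- field(nodes, k)
  structure(list(disp = disp, A = A, center = center, r_inner = r_inner,
                 n_frames = K, field = field, strain_polar = strain_polar,
                 grid = grid),
            class = "ground_truth_motion")
}

#' Simulate a B-mode cine-loop of the pulsating wall
#'
#' Scatterer-based speckle simulation with a coherent/incoherent map design:
#' point scatterers are placed uniformly at random over the image; those
#' inside the wall ring at frame 1 form the coherent map, keep the
#' backscatter coefficient (BSC) assigned from the frame-1 template
#' intensity via [bsc_from_intensity()], and are advected by the analytic
#' ground-truth motion field; scatterers in the background form the
#' incoherent map, stay in place, and take their BSC from the (static)
#' template each frame. A 1 mm transition zone on either side of the wall
#' ring holds no scatterers. Each frame is formed by bilinear splatting of
#' BSC-weighted scatterers, convolution with a Gaussian-modulated axial
#' cosine x Gaussian lateral point-spread function, envelope detection, and
#' 40 dB log compression to 8 bits.
#'
#' @param template a [make_phantom_template()] result.
#' @param motion a [analytic_inflation_motion()] result sharing the
#'   template's geometry.
#' @param n_scatterers scatterers drawn over the image (about 11,000 by
#'   default; at least 100 for meaningful speckle statistics).
#' @param seed RNG seed; identical seeds give bit-identical sequences.
#' @param frame_rate Hz; default spreads the cycle over 1 s.
#' @param psf list of point-spread parameters `sigma_lat_mm`, `sigma_ax_mm`,
#'   `wavelength_mm`, `dynamic_range_db`.
#' @return list with `seq` (a [bmode_sequence()]), `truth` (the motion,
#'   with `$node_positions` `m x K x 2` ground-truth grid-node positions),
#'   `template`, `scatterers` (frame-1 positions, map membership, BSC), and
#'   `envelope1` (pre-compression envelope of frame 1, for speckle
#'   statistics).
#' @export
simulate_bmode <- function(template, motion, n_scatterers = 11000L, seed = 1L,
                           frame_rate = NULL,
                           psf = list(sigma_lat_mm = 0.4, sigma_ax_mm = 0.2,
                                      wavelength_mm = 0.3,
                                      dynamic_range_db = 40)) {
  stopifnot(inherits(template, "phantom_template"),
            inherits(motion, "ground_truth_motion"))
  if (n_scatterers < 100) stop("need at least 100 scatterers for speckle")
  set.seed(seed)
  W <- template$image_size_mm[1]; H <- template$image_size_mm[2]
  dx <- template$pixel_spacing[1]; dy <- template$pixel_spacing[2]
  nr <- nrow(template$img); nc <- ncol(template$img)
  sx <- runif(n_scatterers, 0, W)
  sy <- runif(n_scatterers, 0, H)
  r <- sqrt((sx - template$center[1])^2 + (sy - template$center[2])^2)
  in_wall <- r >= template$r_inner & r <= template$r_outer
  in_transition <- (r >= template$r_inner - 1 & r < template$r_inner) |
    (r > template$r_outer & r <= template$r_outer + 1)
  keep <- !in_transition
  sx <- sx[keep]; sy <- sy[keep]; coh <- in_wall[keep]
  bsc <- bsc_from_intensity(cpp_bilinear(template$img, sx / dx, sy / dy))
  K <- motion$n_frames
  if (is.null(frame_rate)) frame_rate <- (K - 1) / 1.0
  # complex PSF kernel (axial modulation along y)
  rl <- ceiling(3 * psf$sigma_lat_mm / dx)
  ra <- ceiling(3 * psf$sigma_ax_mm / dy)
  kx <- ((-rl):rl) * dx
  ky <- ((-ra):ra) * dy
  envl <- outer(exp(-ky^2 / (2 * psf$sigma_ax_mm^2)),
                exp(-kx^2 / (2 * psf$sigma_lat_mm^2)))
  phase <- 2 * pi * ky / psf$wavelength_mm
  k_re <- envl * cos(phase)
  k_im <- envl * sin(phase)
  # the axial carrier is near Nyquist at clinical pixel sizes; remove the
  # sampling-induced DC so the kernel keeps its bandpass (RF) character
  k_re <- k_re - mean(k_re)
  k_im <- k_im - mean(k_im)
  env <- array(NA_real_, c(nr, nc, K))
  pos0 <- cbind(sx, sy)
  for (k in seq_len(K)) {
    p <- pos0
    if (any(coh)) {
      u <- motion$field(pos0[coh, , drop = FALSE], k)
      p[coh, ] <- pos0[coh, , drop = FALSE] + u
    }
    sp <- cpp_splat_bilinear(nr, nc, p[, 1] / dx, p[, 2] / dy, bsc)
    re <- cpp_filter2_reflect(sp, k_re)
    im <- cpp_filter2_reflect(sp, k_im)
    env[, , k] <- sqrt(re^2 + im^2)
  }
  peak <- max(env)
  dr <- psf$dynamic_range_db
  db <- 20 * log10(pmax(env, peak * 10^(-dr / 20 - 1)) / peak)
  frames <- round(pmin(pmax((db + dr) / dr, 0), 1) * 255)
  sq <- bmode_sequence(frames, template$pixel_spacing, frame_rate)
  nodes0 <- grid_node_matrix(template$grid)
  npos <- array(NA_real_, dim(motion$disp))
  for (k in seq_len(K)) npos[, k, ] <- nodes0 + motion$disp[, k, ]
  truth <- motion
  truth$node_positions <- npos
  list(seq = sq, truth = truth, template = template,
       scatterers = data.frame(x_mm = sx, y_mm = sy, coherent = coh,
                               bsc = bsc),
       envelope1 = env[, , 1])
}
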