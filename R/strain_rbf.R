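#' Fit a cubic RBF + linear polynomial to sparse displacements
#'
#' Interpolates a sparse 2D displacement field with a cubic radial basis
#' function plus a linear polynomial,
#' \deqn{u(x) = \sum_i \gamma_i \|x - x_i\|^3 + \beta_0 + \beta_1 x + \beta_2 y,}
#' solving the symmetric (N+3) x (N+3) saddle-point system
#' `[M P; P' 0] [gamma; beta] = [g; 0]` with `M_ij = ||x_i - x_j||^3` and
#' `P = [1 x y]`, once per displacement component (dense LAPACK solve with
#' partial pivoting; no kernel regularization — exact interpolation at the
#' sources is part of the contract). The orthogonality side conditions
#' `sum(gamma) = sum(gamma x) = sum(gamma y) = 0` are enforced by the
#' constraint block. Sources closer than 1e-6 mm are deduplicated (first
#' occurrence kept, with a message); exactly collinear sources make the
#' system singular and raise an error.
#'
#' @param sources n x 2 matrix of source coordinates, mm.
#' @param displacements n x 2 matrix of known displacements (gx, gy), mm.
#' @return object of class `rbf_model` with fields `sources`, `g`,
#'   `gamma` (n x 2), `beta` (3 x 2).
#' @export
fit_rbf <- function(sources, displacements) {
  x <- as.matrix(sources)
  g <- as.matrix(displacements)
  stopifnot(ncol(x) == 2, ncol(g) == 2, nrow(x) == nrow(g))
  # deduplicate near-coincident sources
  if (nrow(x) > 1) {
    o <- order(x[, 1], x[, 2])
    dup <- logical(nrow(x))
    xo <- x[o, , drop = FALSE]
    close_next <- sqrt(rowSums((xo[-1, , drop = FALSE] - xo[-nrow(xo), , drop = FALSE])^2)) < 1e-6
    dup[o[-1][close_next]] <- TRUE
    if (any(dup)) {
      message(sprintf("fit_rbf: removed %d duplicate source(s)", sum(dup)))
      x <- x[!dup, , drop = FALSE]
      g <- g[!dup, , drop = FALSE]
    }
  }
  n <- nrow(x)
  if (n < 3) stop("need at least 3 distinct sources")
  # collinearity makes [M P; P' 0] singular; detect it up front
  cen <- sweep(x, 2, colMeans(x))
  if (min(svd(cen, nu = 0, nv = 0)$d) < 1e-10 * max(1, max(abs(cen))))
    stop("sources are collinear: RBF system is singular")
  dx <- outer(x[, 1], x[, 1], "-")
  dy <- outer(x[, 2], x[, 2], "-")
  M <- (dx^2 + dy^2)^1.5
  P <- cbind(1, x)
  A <- rbind(cbind(M, P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- rbind(g, matrix(0, 3, 2))
  sol <- solve(A, rhs)
  structure(list(sources = x, g = g,
                 gamma = sol[seq_len(n), , drop = FALSE],
                 beta = sol[n + 1:3, , drop = FALSE]),
            class = "rbf_model")
}

#' @export
print.rbf_model <- function(x, ...) {
  cat(sprintf("rbf_model: cubic kernel + linear polynomial, %d sources\n",
              nrow(x$sources)))
  invisible(x)
}

#' Evaluate an RBF displacement field
#'
#' Direct summation of the fitted kernel expansion plus the linear
#' polynomial at arbitrary target points (interpolation inside the source
#' cloud, smooth extrapolation outside).
#'
#' @param model a [fit_rbf()] result.
#' @param targets m x 2 matrix of evaluation points, mm.
#' @return m x 2 matrix of displacements (ux, uy), mm.
#' @export
eval_displacement <- function(model, targets) {
  tg <- as.matrix(targets)
  dx <- outer(tg[, 1], model$sources[, 1], "-")
  dy <- outer(tg[, 2], model$sources[, 2], "-")
  K <- (dx^2 + dy^2)^1.5
  H <- cbind(1, tg)
  K %*% model$gamma + H %*% model$beta
}

#' Analytic gradient of an RBF displacement field
#'
#' The cubic kernel differentiates in closed form:
#' `d/dx ||r||^3 = 3 ||r|| r_x` (and likewise in y), with the derivative
#' taken as 0 at a target coinciding with a source (the limit). Adding the
#' polynomial slopes gives the material displacement gradient.
#'
#' @param model a [fit_rbf()] result.
#' @param targets m x 2 matrix of evaluation points, mm.
#' @return m x 4 matrix with columns `duxdx, duxdy, duydx, duydy`.
#' @export
eval_gradient <- function(model, targets) {
  tg <- as.matrix(targets)
  dx <- outer(tg[, 1], model$sources[, 1], "-")
  dy <- outer(tg[, 2], model$sources[, 2], "-")
  r <- sqrt(dx^2 + dy^2)
  Kx <- 3 * r * dx          # vanishes smoothly as r -> 0
  Ky <- 3 * r * dy
  cbind(duxdx = as.vector(Kx %*% model$gamma[, 1]) + model$beta[2, 1],
        duxdy = as.vector(Ky %*% model$gamma[, 1]) + model$beta[3, 1],
        duydx = as.vector(Kx %*% model$gamma[, 2]) + model$beta[2, 2],
        duydy = as.vector(Ky %*% model$gamma[, 2]) + model$beta[3, 2])
}

#' Infinitesimal Cartesian strains from a displacement gradient
#'
#' Normal strains are the diagonal gradient entries; the shear is the
#' engineering shear strain `gamma_xy = dux/dy + duy/dx` (twice the
#' tensorial component).
#'
#' @param grad m x 4 matrix as returned by [eval_gradient()], or a length-4
#'   vector for a single point.
#' @return m x 3 matrix with columns `eps_x, eps_y, gamma_xy`.
#' @export
strain_cartesian <- function(grad) {
  if (is.null(dim(grad))) grad <- matrix(grad, 1, 4)
  cbind(eps_x = grad[, 1], eps_y = grad[, 4],
        gamma_xy = grad[, 2] + grad[, 3])
}

#' Rotate Cartesian strains into local polar components
#'
#' Applies the tensor rotation by the local tangent angle theta,
#' `T = [m^2 n^2 2mn; n^2 m^2 -2mn; -mn mn m^2-n^2]` with `m = cos(theta)`,
#' `n = sin(theta)`, acting on the half-shear vector
#' `(eps_x, eps_y, gamma_xy/2)` and returning
#' `(eps_circ, eps_rad, eps_shear/2)` scaled back to the engineering shear.
#' Positive `eps_circ` is circumferential stretch; positive `eps_rad` is
#' wall thickening.
#'
#' @param eps m x 3 matrix `(eps_x, eps_y, gamma_xy)` or length-3 vector.
#' @param theta tangent angle(s), radians (recycled to m).
#' @return m x 3 matrix with columns `eps_circ, eps_rad, eps_shear`.
#' @export
rotate_to_polar <- function(eps, theta) {
  if (is.null(dim(eps))) eps <- matrix(eps, 1, 3)
  m <- cos(theta); n <- sin(theta)
  ex <- eps[, 1]; ey <- eps[, 2]; hxy <- eps[, 3] / 2
  circ <- m^2 * ex + n^2 * ey + 2 * m * n * hxy
  rad <- n^2 * ex + m^2 * ey - 2 * m * n * hxy
  shear_half <- -m * n * ex + m * n * ey + (m^2 - n^2) * hxy
  cbind(eps_circ = circ, eps_rad = rad, eps_shear = 2 * shear_half)
}

#' Map strains on the wall grid for every frame of a cycle
#'
#' For each frame of the tracked cycle, fits an RBF model to the cumulative
#' displacements of all tracked points since the cycle's first frame
#' (sources are the positions at that first frame), evaluates the analytic
#' displacement gradient at the grid nodes, forms Cartesian strains, and
#' rotates them into local circumferential/radial/shear components using the
#' grid tangent angles. Strain at the cycle's first frame is identically
#' zero by construction. Grid nodes outside the convex hull of sources rely
#' on the RBF's smooth extrapolation.
#'
#' @param track a merged `track_result` over the cycle.
#' @param grid the [build_wall_grid()] output grid.
#' @return object of class `strain_field_set`: list with `frames`, `grid`
#'   and `fields`, one `m x 9` matrix per frame with columns
#'   `eps_x, eps_y, gamma_xy, eps_circ, eps_rad, eps_shear,
#'   duxdx, duxdy, duydx` + `duydy` (m = number of grid nodes, layer-major).
#' @export
map_strains <- function(track, grid) {
  stopifnot(inherits(track, "track_result"), inherits(grid, "wall_grid"))
  src <- track$positions[, 1, , drop = TRUE]
  nodes <- grid_node_matrix(grid)
  theta <- as.vector(t(grid$theta))
  K <- dim(track$positions)[2]
  fields <- vector("list", K)
  for (k in seq_len(K)) {
    if (k == 1) {
      z <- matrix(0, nrow(nodes), 10)
    } else {
      disp <- track$displacements[, k, , drop = TRUE]
      model <- fit_rbf(src, disp)
      gr <- eval_gradient(model, nodes)
      eps <- strain_cartesian(gr)
      pol <- rotate_to_polar(eps, theta)
      z <- cbind(eps, pol, gr)
    }
    colnames(z) <- c("eps_x", "eps_y", "gamma_xy",
                     "eps_circ", "eps_rad", "eps_shear",
                     "duxdx", "duxdy", "duydx", "duydy")
    fields[[k]] <- z
  }
  structure(list(frames = track$frames, grid = grid, fields = fields),
            class = "strain_field_set")
}

#' @export
print.strain_field_set <- function(x, ...) {
  rng <- range(vapply(x$fields, function(f) range(f[, "eps_circ"]), numeric(2)))
  cat(sprintf("strain_field_set: %d frames, eps_circ in [%.4f, %.4f]\n",
              length(x$fields), rng[1], rng[2]))
  invisible(x)
}

#' Long-format strain table
#'
#' @param sf a [map_strains()] result.
#' @return data frame `frame, layer, index, eps_circ, eps_rad, eps_shear,
#'   eps_x, eps_y, gamma_xy`.
#' @export
strain_table <- function(sf) {
  g <- sf$grid
  base <- data.frame(layer = rep(seq_len(g$n_layers), each = g$n_points),
                     index = rep(seq_len(g$n_points), g$n_layers))
  do.call(rbind, lapply(seq_along(sf$fields), function(k) {
    f <- sf$fields[[k]]
    cbind(frame = sf$frames[k], base,
          as.data.frame(f[, c("eps_circ", "eps_rad", "eps_shear",
                              "eps_x", "eps_y", "gamma_xy")]))
  }))
}

#' Overlay a circumferential strain field on a B-mode frame
#'
#' Writes a PNG with the frame in gray and the grid nodes colored by
#' `eps_circ` on a symmetric diverging scale (blue = stretch, red =
#' shortening), mirroring the usual clinical display.
#'
#' @param sf a [map_strains()] result.
#' @param seq the [bmode_sequence()] the strains were computed on.
#' @param frame_index index into `sf$frames` to draw.
#' @param path output PNG path.
#' @param limit symmetric color-scale limit; default the max |eps_circ| over
#'   the cycle.
#' @return `path`, invisibly.
#' @export
plot_strain_overlay <- function(sf, seq, frame_index, path, limit = NULL) {
  f <- sf$fields[[frame_index]]
  if (is.null(limit))
    limit <- max(abs(vapply(sf$fields, function(z) max(abs(z[, "eps_circ"])), numeric(1))), 1e-9)
  img <- seq$frames[, , sf$frames[frame_index]]
  nodes <- grid_node_matrix(sf$grid)
  dx <- seq$pixel_spacing[1]; dy <- seq$pixel_spacing[2]
  grDevices::png(path, width = ncol(img) * 3, height = nrow(img) * 3)
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
  graphics::image(x = (seq_len(ncol(img)) - 1) * dx,
                  y = (seq_len(nrow(img)) - 1) * dy,
                  z = t(img)[, nrow(img):1],
                  col = grDevices::gray.colors(256, 0, 1), useRaster = TRUE,
                  asp = 1, axes = FALSE, xlab = "", ylab = "")
  ymax <- (nrow(img) - 1) * dy
  v <- pmin(pmax(f[, "eps_circ"] / limit, -1), 1)
  pal <- grDevices::colorRampPalette(c("red", "white", "blue"))(255)
  cols <- pal[round((v + 1) / 2 * 254) + 1]
  graphics::points(nodes[, 1], ymax - nodes[, 2], col = cols, pch = 15, cex = 0.8)
  invisible(path)
}
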