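#' Closed inner-wall contour
#'
#' Constructs a closed 2D contour in millimetres, image convention: origin at
#' the top-left of the scan, x to the right (patient's anatomic left), y
#' downward (posterior). Orientation is normalized so the shoelace signed
#' area of the stored coordinates is positive; the most posterior point is
#' the one with maximum y.
#'
#' @param points numeric matrix or data frame with two columns (x, y) in mm.
#' @param closed logical; contours are closed vessel perimeters.
#' @return an object of class `wall_contour`.
#' @export
wall_contour <- function(points, closed = TRUE) {
  pts <- as.matrix(points)
  if (ncol(pts) != 2) stop("contour points must have two columns (x, y)")
  storage.mode(pts) <- "double"
  if (any(!is.finite(pts))) stop("contour points must be finite")
  # drop consecutive coincident points (incl. an explicit closing repeat)
  n <- nrow(pts)
  if (n > 1) {
    d <- sqrt(rowSums((pts - pts[c(2:n, 1), , drop = FALSE])^2))
    keep <- rep(TRUE, n)
    keep[which(d[-n] < 1e-9) + 1] <- FALSE
    if (d[n] < 1e-9 && sum(keep) > 1) keep[n] <- FALSE
    pts <- pts[keep, , drop = FALSE]
  }
  if (nrow(pts) < 3) stop("a contour needs at least 3 distinct points")
  if (closed && contour_area(pts) < 0) pts <- pts[c(1, nrow(pts):2), , drop = FALSE]
  colnames(pts) <- c("x", "y")
  structure(list(points = pts, closed = closed), class = "wall_contour")
}

#' @export
print.wall_contour <- function(x, ...) {
  cat(sprintf("wall_contour: %d points, %s, perimeter %.2f mm\n",
              nrow(x$points), if (x$closed) "closed" else "open",
              contour_perimeter(x$points)))
  invisible(x)
}

# shoelace signed area of a polygon (closing edge implied)
contour_area <- function(pts) {
  n <- nrow(pts)
  i2 <- c(2:n, 1)
  sum(pts[, 1] * pts[i2, 2] - pts[i2, 1] * pts[, 2]) / 2
}

contour_perimeter <- function(pts) {
  n <- nrow(pts)
  sum(sqrt(rowSums((pts[c(2:n, 1), , drop = FALSE] - pts)^2)))
}

contour_centroid <- function(pts) colMeans(pts)

# Dense periodic-spline polyline through ordered landmarks.
# Returns list(x, y, s) with s the cumulative arc length (s[1] = 0).
dense_periodic_curve <- function(pts, n_dense) {
  n <- nrow(pts)
  chord <- sqrt(rowSums((pts[c(2:n, 1), , drop = FALSE] - pts)^2))
  tt <- c(0, cumsum(chord))            # length n + 1, closing at tt[n+1]
  xs <- c(pts[, 1], pts[1, 1])
  ys <- c(pts[, 2], pts[1, 2])
  fx <- stats::splinefun(tt, xs, method = "periodic")
  fy <- stats::splinefun(tt, ys, method = "periodic")
  te <- seq(0, tt[n + 1], length.out = n_dense + 1)[-(n_dense + 1)]
  xd <- fx(te); yd <- fy(te)
  list(x = xd, y = yd)
}

#' Resample a contour to equally spaced points
#'
#' Fits a periodic cubic spline through the ordered landmarks and discretizes
#' it to `n_points` equally spaced in arc length. The most posterior point of
#' the curve (maximum y in image coordinates) becomes node 1. Arc length is
#' measured on a dense polyline subdivision (1000x oversampling).
#'
#' @param landmarks a [wall_contour()] or a two-column matrix of (x, y) mm.
#' @param n_points number of output points.
#' @return a [wall_contour()] with `n_points` points.
#' @export
resample_contour <- function(landmarks, n_points) {
  if (inherits(landmarks, "wall_contour")) landmarks <- landmarks$points
  pts <- as.matrix(landmarks)
  if (nrow(pts) >= 2) {
    # strip an explicit closing repeat before the landmark-count check
    if (sqrt(sum((pts[1, ] - pts[nrow(pts), ])^2)) < 1e-9)
      pts <- pts[-nrow(pts), , drop = FALSE]
  }
  if (nrow(pts) < 3) stop("contour resampling needs at least 3 landmarks")
  if (n_points < 3) stop("n_points must be >= 3")
  nd <- 1000L * as.integer(n_points)
  cur <- dense_periodic_curve(pts, nd)
  # root the discretization at the most posterior point (max y)
  i0 <- which.max(cur$y)
  ord <- c(i0:nd, seq_len(i0 - 1L))
  xd <- cur$x[ord]; yd <- cur$y[ord]
  seg <- sqrt(diff(c(xd, xd[1]))^2 + diff(c(yd, yd[1]))^2)
  s <- c(0, cumsum(seg))               # length nd + 1, total at the end
  total <- s[nd + 1]
  st <- (seq_len(n_points) - 1) * total / n_points
  xo <- stats::approx(s, c(xd, xd[1]), xout = st)$y
  yo <- stats::approx(s, c(yd, yd[1]), xout = st)$y
  wall_contour(cbind(xo, yo))
}

# Outward unit normals at each node: average of the two 90deg-rotated
# adjacent-chord directions, oriented away from the contour centroid.
contour_normals <- function(pts) {
  n <- nrow(pts)
  prv <- pts[c(n, 1:(n - 1)), , drop = FALSE]
  nxt <- pts[c(2:n, 1), , drop = FALSE]
  rot90 <- function(v) cbind(-v[, 2], v[, 1])
  unit <- function(v) v / pmax(sqrt(rowSums(v^2)), 1e-12)
  nn <- unit(unit(rot90(pts - prv)) + unit(rot90(nxt - pts)))
  cen <- contour_centroid(pts)
  out <- rowSums(nn * sweep(pts, 2, cen)) < 0
  nn[out, ] <- -nn[out, , drop = FALSE]
  nn
}

# O(n^2) proper-crossing test between non-adjacent polygon edges
polygon_self_intersects <- function(pts) {
  n <- nrow(pts)
  a <- pts
  b <- pts[c(2:n, 1), , drop = FALSE]
  cross2 <- function(ox, oy, px, py, qx, qy) (px - ox) * (qy - oy) - (py - oy) * (qx - ox)
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    js <- js[!(i == 1 & js == n)]     # skip edges sharing a vertex
    if (!length(js)) next
    d1 <- cross2(a[i, 1], a[i, 2], b[i, 1], b[i, 2], a[js, 1], a[js, 2])
    d2 <- cross2(a[i, 1], a[i, 2], b[i, 1], b[i, 2], b[js, 1], b[js, 2])
    d3 <- cross2(a[js, 1], a[js, 2], b[js, 1], b[js, 2], rep(a[i, 1], length(js)), rep(a[i, 2], length(js)))
    d4 <- cross2(a[js, 1], a[js, 2], b[js, 1], b[js, 2], rep(b[i, 1], length(js)), rep(b[i, 2], length(js)))
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

#' Build the wall region-of-interest grid
#'
#' Projects each inner-wall node outward along the local normal by the wall
#' thickness to form the outer layer (the normal is the average of the two
#' 90-degree-rotated adjacent chords), re-resamples the outer contour to N
#' equally spaced points keeping the most posterior point fixed, and fills
#' intermediate layers by linear partition of the inner-to-outer segments.
#' When `n_points` is `NULL`, N is chosen so the element aspect ratio is
#' close to 1: circumferential spacing approximately equal to
#' `thickness / (n_layers - 1)`, rounded to the nearest even integer, at
#' least 16.
#'
#' @param inner inner-wall [wall_contour()].
#' @param thickness wall thickness in mm (a homogeneous 2 mm is the standard
#'   assumption since thickness cannot be estimated from B-mode images).
#' @param n_layers number of grid layers (inner wall = layer 1).
#' @param n_points circumferential node count; `NULL` for automatic.
#' @return an object of class `wall_grid` with fields `nodes`
#'   (`n_layers x N x 2` array, mm), `theta` (`n_layers x N` local tangent
#'   angles, radians), `thickness`, `n_layers`, `n_points`.
#' @export
build_wall_grid <- function(inner, thickness = 2.0, n_layers = 4L, n_points = NULL) {
  if (!inherits(inner, "wall_contour")) inner <- wall_contour(inner)
  if (!inner$closed) stop("inner contour must be closed")
  if (n_layers < 2) stop("need at least 2 layers")
  if (is.null(n_points)) {
    spacing <- thickness / (n_layers - 1)
    n_points <- max(16L, 2L * as.integer(round(contour_perimeter(inner$points) / spacing / 2)))
  }
  inner_rs <- resample_contour(inner, n_points)
  pin <- inner_rs$points
  nrm <- contour_normals(pin)
  outer_raw <- pin + thickness * nrm
  if (polygon_self_intersects(outer_raw))
    warning("outer contour self-intersects (tortuous wall); proceeding")
  outer_rs <- resample_contour(outer_raw, n_points)
  pout <- outer_rs$points
  nodes <- array(NA_real_, c(n_layers, n_points, 2))
  for (l in seq_len(n_layers)) {
    f <- (l - 1) / (n_layers - 1)
    nodes[l, , ] <- (1 - f) * pin + f * pout
  }
  g <- structure(list(nodes = nodes, thickness = thickness,
                      n_layers = n_layers, n_points = n_points,
                      inner = inner_rs, outer = outer_rs),
                 class = "wall_grid")
  g$theta <- tangent_angles(g)
  g
}

#' @export
print.wall_grid <- function(x, ...) {
  cat(sprintf("wall_grid: %d layers x %d points, thickness %.2f mm\n",
              x$n_layers, x$n_points, x$thickness))
  invisible(x)
}

#' Local tangent angles of a wall grid
#'
#' Angle of the local circumferential tangent with respect to the horizontal
#' axis, per node, from periodic central differences along each layer.
#' Because the polar strain rotation is pi-periodic in the tangent angle,
#' angles are wrapped to (-pi/2, pi/2].
#'
#' @param grid a [build_wall_grid()] result.
#' @return `n_layers x N` matrix of angles in radians.
#' @export
tangent_angles <- function(grid) {
  stopifnot(inherits(grid, "wall_grid"))
  n <- grid$n_points
  th <- matrix(NA_real_, grid$n_layers, n)
  for (l in seq_len(grid$n_layers)) {
    p <- grid$nodes[l, , , drop = TRUE]
    tx <- p[c(2:n, 1), 1] - p[c(n, 1:(n - 1)), 1]
    ty <- p[c(2:n, 1), 2] - p[c(n, 1:(n - 1)), 2]
    a <- atan2(ty, tx)
    a[a > pi / 2] <- a[a > pi / 2] - pi
    a[a <= -pi / 2] <- a[a <= -pi / 2] + pi
    th[l, ] <- a
  }
  th
}

#' Flatten a wall grid to a node table
#'
#' @param x a `wall_grid`.
#' @param ... unused.
#' @return data frame with columns `layer`, `index`, `x_mm`, `y_mm`,
#'   `theta_rad`; nodes ordered by layer, then circumferential index.
#' @export
as.data.frame.wall_grid <- function(x, ...) {
  data.frame(
    layer = rep(seq_len(x$n_layers), each = x$n_points),
    index = rep(seq_len(x$n_points), x$n_layers),
    x_mm = as.vector(t(x$nodes[, , 1])),
    y_mm = as.vector(t(x$nodes[, , 2])),
    theta_rad = as.vector(t(x$theta))
  )
}

# All grid nodes as an (n_layers * N) x 2 matrix, layer-major order
# (matches as.data.frame.wall_grid).
grid_node_matrix <- function(grid) {
  cbind(as.vector(t(grid$nodes[, , 1])), as.vector(t(grid$nodes[, , 2])))
}

# Even-odd (ray crossing) point-in-polygon test, vectorized over points.
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi + 1e-300) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Pixel mask of the wall region of interest
#'
#' Marks pixels lying inside the wall ring (inside the outer contour, outside
#' the inner contour) of a wall grid, on an image of `dim` pixels with pixel
#' spacing `spacing` mm/px (pixel centers at 0-based index * spacing).
#'
#' @param grid a `wall_grid`.
#' @param dim integer vector `c(n_rows, n_cols)`.
#' @param spacing numeric length-2, mm per pixel in (x, y).
#' @return logical matrix of dimension `dim`.
#' @export
roi_mask <- function(grid, dim, spacing) {
  stopifnot(inherits(grid, "wall_grid"))
  nr <- dim[1]; nc <- dim[2]
  px <- rep((seq_len(nc) - 1) * spacing[1], each = nr)
  py <- rep((seq_len(nr) - 1) * spacing[2], nc)
  m <- point_in_polygon(px, py, grid$outer$points) &
    !point_in_polygon(px, py, grid$inner$points)
  matrix(m, nr, nc)
}
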