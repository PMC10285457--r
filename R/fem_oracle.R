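#' Bilinear quadrilateral strain at the centroid (reduced integration)
#'
#' Strain of a 4-node isoparametric quadrilateral from nodal displacements,
#' evaluated at the single reduced-integration point (xi, eta) = (0, 0),
#' which coincides with the element centroid — the location where the
#' bilinear element is most accurate. Shape functions
#' `N_a = 1/4 (1 + xi_a xi)(1 + eta_a eta)`; physical derivatives through
#' the inverse Jacobian. An optional 2x2 full-integration variant averages
#' the strain over the four Gauss points.
#'
#' @param nodes 4 x 2 matrix of corner coordinates, counter-clockwise, mm.
#' @param nodal_u 4 x 2 matrix of nodal displacements, mm.
#' @param integration `"reduced"` (centroid) or `"full"` (2x2 Gauss average).
#' @return named vector `(eps_x, eps_y, gamma_xy)`.
#' @export
bilinear_strain <- function(nodes, nodal_u, integration = c("reduced", "full")) {
  integration <- match.arg(integration)
  nodes <- as.matrix(nodes); nodal_u <- as.matrix(nodal_u)
  stopifnot(nrow(nodes) == 4, ncol(nodes) == 2,
            nrow(nodal_u) == 4, ncol(nodal_u) == 2)
  xi_a <- c(-1, 1, 1, -1)
  eta_a <- c(-1, -1, 1, 1)
  pts <- if (integration == "reduced") {
    matrix(c(0, 0), 1, 2)
  } else {
    g <- 1 / sqrt(3)
    cbind(c(-g, g, g, -g), c(-g, -g, g, g))
  }
  acc <- c(0, 0, 0)
  for (q in seq_len(nrow(pts))) {
    xi <- pts[q, 1]; eta <- pts[q, 2]
    dNdxi <- 0.25 * xi_a * (1 + eta_a * eta)
    dNdeta <- 0.25 * eta_a * (1 + xi_a * xi)
    J <- rbind(c(sum(dNdxi * nodes[, 1]), sum(dNdxi * nodes[, 2])),
               c(sum(dNdeta * nodes[, 1]), sum(dNdeta * nodes[, 2])))
    detJ <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
    if (detJ <= 0) stop("degenerate element: non-positive Jacobian")
    dN <- solve(J, rbind(dNdxi, dNdeta))   # rows: d/dx, d/dy
    ex <- sum(dN[1, ] * nodal_u[, 1])
    ey <- sum(dN[2, ] * nodal_u[, 2])
    gxy <- sum(dN[2, ] * nodal_u[, 1]) + sum(dN[1, ] * nodal_u[, 2])
    acc <- acc + c(ex, ey, gxy)
  }
  out <- acc / nrow(pts)
  names(out) <- c("eps_x", "eps_y", "gamma_xy")
  out
}

#' Maximum principal strain
#'
#' Larger eigenvalue of the 2D infinitesimal strain tensor:
#' `(eps_x + eps_y)/2 + sqrt(((eps_x - eps_y)/2)^2 + (gamma_xy/2)^2)`.
#'
#' @param eps_x,eps_y,gamma_xy strain components (vectorized), or `eps_x`
#'   may be an m x 3 matrix.
#' @return numeric vector of maximum principal strains.
#' @export
max_principal <- function(eps_x, eps_y = NULL, gamma_xy = NULL) {
  if (is.null(eps_y)) {
    m <- as.matrix(eps_x)
    eps_x <- m[, 1]; eps_y <- m[, 2]; gamma_xy <- m[, 3]
  }
  (eps_x + eps_y) / 2 + sqrt(((eps_x - eps_y) / 2)^2 + (gamma_xy / 2)^2)
}

# Quadrilateral elements of a wall grid: element (l, i) has corners
# (l,i), (l,i+1), (l+1,i+1), (l+1,i) (periodic in i), re-ordered to a
# positive Jacobian. Returns list of index matrices into the layer-major
# node numbering, plus centroids.
grid_elements <- function(grid) {
  L <- grid$n_layers; N <- grid$n_points
  node_id <- function(l, i) (l - 1) * N + ((i - 1) %% N) + 1
  nodes <- grid_node_matrix(grid)
  els <- vector("list", (L - 1) * N)
  cent <- matrix(NA_real_, (L - 1) * N, 2)
  k <- 0
  for (l in seq_len(L - 1)) for (i in seq_len(N)) {
    ids <- c(node_id(l, i), node_id(l, i + 1), node_id(l + 1, i + 1), node_id(l + 1, i))
    p <- nodes[ids, , drop = FALSE]
    if (contour_area(p) < 0) ids <- rev(ids)   # enforce CCW corner order
    k <- k + 1
    els[[k]] <- ids
    cent[k, ] <- colMeans(nodes[ids, , drop = FALSE])
  }
  list(ids = els, centroids = cent, nodes = nodes)
}

# FEM max-principal strain at every element centroid of a grid, given nodal
# displacements (layer-major m x 2 matrix)
fem_grid_strain <- function(grid, nodal_u, integration = "reduced") {
  ge <- grid_elements(grid)
  eps <- t(vapply(ge$ids, function(ids)
    bilinear_strain(ge$nodes[ids, , drop = FALSE],
                    nodal_u[ids, , drop = FALSE], integration),
    numeric(3)))
  list(centroids = ge$centroids, eps = eps, max_principal = max_principal(eps))
}

# Nodal FEM strain map: integration-point (centroid) values extrapolated to
# the nodes by averaging over the elements sharing each node — the standard
# display step for single-Gauss-point elements.
fem_nodal_max_principal <- function(grid, nodal_u, integration = "reduced") {
  ge <- grid_elements(grid)
  fem <- fem_grid_strain(grid, nodal_u, integration)
  acc <- rep(0, nrow(ge$nodes))
  cnt <- rep(0L, nrow(ge$nodes))
  for (e in seq_along(ge$ids)) {
    ids <- ge$ids[[e]]
    acc[ids] <- acc[ids] + fem$max_principal[e]
    cnt[ids] <- cnt[ids] + 1L
  }
  acc / cnt
}

# RBF max-principal strain at the element centroids of a grid, fitted on the
# grid nodes with the given nodal displacements
rbf_grid_strain <- function(grid, nodal_u, targets = NULL) {
  if (is.null(targets)) targets <- grid_elements(grid)$centroids
  model <- fit_rbf(grid_node_matrix(grid), nodal_u)
  eps <- strain_cartesian(eval_gradient(model, targets))
  list(centroids = targets, eps = eps, max_principal = max_principal(eps))
}

#' Mesh-convergence study of the maximum principal strain
#'
#' For each element size, builds a wall grid on the given inner contour with
#' radial and circumferential spacing close to that size, samples the
#' displacement field at the nodes, and computes the field maximum of the
#' nodal maximum-principal-strain map by two routes: cubic RBF fit +
#' analytic differentiation evaluated at the nodes, and bilinear
#' reduced-integration shape functions with the integration-point values
#' extrapolated to the nodes (the standard display step for these
#' elements). Each method's curve is normalized by its own finest-grid
#' value.
#'
#' @param inner inner-wall [wall_contour()] of the benchmark geometry.
#' @param field function `(m x 2 matrix of points) -> m x 2 displacements`.
#' @param element_sizes element sizes to test, mm (coarse to fine).
#' @param thickness wall thickness, mm; element sizes above it are rejected.
#' @param integration FEM integration scheme, `"reduced"` or `"full"`.
#' @return data frame `method, element_size_mm, n_elements,
#'   max_principal_strain, normalized`.
#' @export
mesh_convergence <- function(inner, field, element_sizes, thickness = 2.0,
                             integration = "reduced") {
  if (any(element_sizes > thickness))
    stop("element size larger than the wall thickness")
  element_sizes <- sort(element_sizes, decreasing = TRUE)
  rows <- lapply(element_sizes, function(h) {
    n_layers <- max(2L, as.integer(round(thickness / h)) + 1L)
    grid <- build_wall_grid(inner, thickness = thickness, n_layers = n_layers)
    nodes <- grid_node_matrix(grid)
    u <- field(nodes)
    n_el <- (n_layers - 1L) * grid$n_points
    data.frame(
      method = c("rbf", "fem"),
      element_size_mm = h,
      n_elements = n_el,
      max_principal_strain = c(max(rbf_grid_strain(grid, u, targets = nodes)$max_principal),
                               max(fem_nodal_max_principal(grid, u, integration)))
    )
  })
  out <- do.call(rbind, rows)
  finest <- element_sizes[length(element_sizes)]
  for (m in unique(out$method)) {
    ref <- out$max_principal_strain[out$method == m &
                                      out$element_size_mm == finest]
    out$normalized[out$method == m] <-
      out$max_principal_strain[out$method == m] / ref
  }
  out
}
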