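#' Sobel gradient magnitude of a frame
#'
#' Per-pixel sum of the absolute responses of the two 3x3 Sobel kernels
#' (|Gx| + |Gy|), with mirror-reflected borders.
#'
#' @param frame numeric matrix (grayscale image, rows = y, cols = x).
#' @return numeric matrix of the same dimension.
#' @export
sobel_gradient <- function(frame) {
  frame <- as.matrix(frame)
  storage.mode(frame) <- "double"
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)   # d/dx (columns)
  ky <- t(kx)                                           # d/dy (rows)
  abs(cpp_filter2_reflect(frame, kx)) + abs(cpp_filter2_reflect(frame, ky))
}

#' Select high-gradient tracking points inside the wall ROI
#'
#' Greedy selection of tracking points in descending order of image gradient,
#' restricted to pixels inside (or on the edge of) the wall region of
#' interest. A candidate is accepted only if it lies at least `min_dist`
#' (default 1 mm) from every previously accepted point, which bounds point
#' clustering and the tracking cost. Ties in gradient value are broken by
#' row-major pixel order, so the selection is deterministic.
#'
#' @param gradient gradient-magnitude image (e.g. from [sobel_gradient()]).
#' @param roi logical matrix of the same dimension marking ROI pixels, e.g.
#'   from [roi_mask()], or a `wall_grid` (mask computed internally).
#' @param spacing pixel spacing `c(dx, dy)` in mm/px.
#' @param min_dist minimum pairwise distance between selected points, mm.
#' @param max_points maximum number of points to select; default 3x the
#'   number of grid nodes when `roi` is a `wall_grid`, otherwise unlimited.
#' @param grid optional `wall_grid` whose nodes are appended to the returned
#'   set (the strain output support must always be tracked); implied when
#'   `roi` is a `wall_grid`.
#' @return object of class `point_set`: list with `points` (n x 2 matrix,
#'   mm), `scores` (gradient magnitude; appended grid nodes get score `NA`),
#'   `n_selected` (count before grid-node append).
#' @export
select_points <- function(gradient, roi, spacing, min_dist = 1.0,
                          max_points = NULL, grid = NULL) {
  if (inherits(roi, "wall_grid")) {
    grid <- roi
    roi <- roi_mask(grid, dim(gradient), spacing)
  }
  stopifnot(all(dim(gradient) == dim(roi)))
  if (!any(roi)) stop("empty ROI: no pixels to select from")
  if (is.null(max_points)) {
    max_points <- if (!is.null(grid)) 3L * grid$n_layers * grid$n_points else Inf
  }
  idx <- which(roi & gradient > 0)
  if (length(idx) == 0) {
    # zero-gradient ROI: fall back to the grid nodes themselves
    if (is.null(grid)) stop("ROI has zero gradient and no grid fallback")
    message("ROI gradient is zero everywhere; falling back to grid nodes")
    nm <- grid_node_matrix(grid)
    return(structure(list(points = nm, scores = rep(NA_real_, nrow(nm)),
                          n_selected = 0L), class = "point_set"))
  }
  nr <- nrow(gradient)
  rows <- (idx - 1) %% nr + 1
  cols <- (idx - 1) %/% nr + 1
  sc <- gradient[idx]
  ord <- order(-sc, rows, cols)
  xs <- (cols[ord] - 1) * spacing[1]
  ys <- (rows[ord] - 1) * spacing[2]
  sc <- sc[ord]
  accx <- numeric(0); accy <- numeric(0); accs <- numeric(0)
  md2 <- min_dist^2
  for (k in seq_along(xs)) {
    if (length(accx) >= max_points) break
    if (length(accx) == 0 ||
        min((accx - xs[k])^2 + (accy - ys[k])^2) >= md2) {
      accx <- c(accx, xs[k]); accy <- c(accy, ys[k]); accs <- c(accs, sc[k])
    }
  }
  pts <- cbind(accx, accy)
  scores <- accs
  n_sel <- nrow(pts)
  if (!is.null(grid)) {
    nm <- grid_node_matrix(grid)
    pts <- rbind(pts, nm)
    scores <- c(scores, rep(NA_real_, nrow(nm)))
  }
  dimnames(pts) <- list(NULL, c("x", "y"))
  structure(list(points = pts, scores = scores, n_selected = n_sel),
            class = "point_set")
}

#' @export
print.point_set <- function(x, ...) {
  cat(sprintf("point_set: %d points (%d gradient-selected)\n",
              nrow(x$points), x$n_selected))
  invisible(x)
}
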