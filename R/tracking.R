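#' B-mode cine-loop sequence
#'
#' @param frames numeric array `n_rows x n_cols x n_frames`, intensities in
#'   0..255 (8-bit grayscale).
#' @param pixel_spacing `c(dx, dy)` in mm/px.
#' @param frame_rate frames per second (Hz).
#' @return object of class `bmode_sequence`.
#' @export
bmode_sequence <- function(frames, pixel_spacing, frame_rate) {
  stopifnot(length(dim(frames)) == 3, dim(frames)[3] >= 2,
            all(pixel_spacing > 0), frame_rate > 0)
  if (min(frames) < 0 || max(frames) > 255)
    stop("frame intensities must lie in [0, 255]")
  structure(list(frames = frames, pixel_spacing = as.numeric(pixel_spacing),
                 frame_rate = as.numeric(frame_rate)),
            class = "bmode_sequence")
}

#' @export
print.bmode_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("bmode_sequence: %d frames of %dx%d px, %.3g x %.3g mm/px, %.3g Hz\n",
              d[3], d[1], d[2], x$pixel_spacing[1], x$pixel_spacing[2],
              x$frame_rate))
  invisible(x)
}

#' Demons tracker parameters
#'
#' Defaults: 9x9 px matching patch, demons normalization `alpha = 1`, up to
#' 50 iterations stopped at a 0.01 px update, Gaussian pre-filter sigma 1 px,
#' Gaussian spatial smoothing of the sparse increments with sigma 2 mm, and a
#' 2-level image pyramid (full and half resolution) to capture motion above
#' the patch scale.
#'
#' @param patch matching patch side in px (odd).
#' @param alpha demons normalization weight on the squared intensity mismatch.
#' @param max_iter maximum demons iterations per point and frame pair.
#' @param tol convergence tolerance on the update, px.
#' @param blur_sigma Gaussian pre-filter sigma, px.
#' @param smooth_sigma_mm sigma of the Gaussian spatial smoothing of the
#'   per-point increments, mm ("Gaussian model of the motion").
#' @param pyramid_levels number of pyramid levels (1 = no pyramid).
#' @return list of class `tracking_params`.
#' @export
tracking_params <- function(patch = 9L, alpha = 1.0, max_iter = 50L,
                            tol = 0.01, blur_sigma = 1.0,
                            smooth_sigma_mm = 2.0, pyramid_levels = 2L) {
  stopifnot(patch %% 2 == 1, patch >= 3, max_iter >= 1, tol > 0,
            pyramid_levels >= 1)
  structure(list(patch = as.integer(patch), alpha = alpha,
                 max_iter = as.integer(max_iter), tol = tol,
                 blur_sigma = blur_sigma, smooth_sigma_mm = smooth_sigma_mm,
                 pyramid_levels = as.integer(pyramid_levels)),
            class = "tracking_params")
}

# decimate an image by 2 after a sigma-1 anti-alias blur
pyr_down <- function(img) {
  b <- cpp_gauss_blur(img, 1.0)
  b[seq(1, nrow(b), 2), seq(1, ncol(b), 2), drop = FALSE]
}

# demons increment (px) for one frame pair over a pyramid
pair_increment <- function(levels0, levels1, px, py, params) {
  nlev <- length(levels0)
  ux <- rep(0, length(px)); uy <- rep(0, length(px))
  any_left <- FALSE
  for (lev in nlev:1) {
    sc <- 2^(lev - 1)
    res <- cpp_demons_pair(levels0[[lev]], levels1[[lev]],
                           px / sc, py / sc, ux / sc, uy / sc,
                           params$patch, params$alpha, params$max_iter,
                           params$tol)
    ux <- res$ux * sc
    uy <- res$uy * sc
    if (lev == 1 && any(!res$ok)) {
      ux[!res$ok] <- 0
      uy[!res$ok] <- 0
      any_left <- TRUE
    }
  }
  list(ux = ux, uy = uy, left = any_left)
}

# Gaussian-weighted spatial smoothing of sparse per-point increments (mm)
smooth_increments <- function(pos_mm, inc_mm, sigma_mm) {
  if (sigma_mm <= 0) return(inc_mm)
  d2 <- outer(pos_mm[, 1], pos_mm[, 1], "-")^2 +
    outer(pos_mm[, 2], pos_mm[, 2], "-")^2
  w <- exp(-d2 / (2 * sigma_mm^2))
  sw <- rowSums(w)
  cbind((w %*% inc_mm[, 1]) / sw, (w %*% inc_mm[, 2]) / sw)
}

#' Track sparse points across a frame range
#'
#' Demons-style frame-to-frame tracking of a sparse point set. For each
#' consecutive frame pair the incremental displacement of every point
#' minimizes a local intensity-matching energy over a square patch (with
#' subpixel bilinear interpolation), estimated coarse-to-fine on an image
#' pyramid; the per-point increments are then smoothed across points with a
#' Gaussian kernel in space, so the sparse displacement field is inherently
#' smooth. Positions accumulate increments. Points that drift outside the
#' image keep their last displacement (with a warning).
#'
#' @param seq a [bmode_sequence()].
#' @param points a `point_set` or an n x 2 matrix of (x, y) positions in mm
#'   at the first frame of `frame_range`.
#' @param params a [tracking_params()].
#' @param frame_range integer vector of frame indices to track, in tracking
#'   order (pass a decreasing range for backward tracking); default all
#'   frames forward.
#' @return object of class `track_result`: `positions` and `displacements`
#'   are `n x K x 2` arrays (mm; displacements relative to the first tracked
#'   frame), `frames` the frame indices in tracking order, `direction` one of
#'   `"forward"`/`"backward"`.
#' @export
track_points <- function(seq, points, params = tracking_params(),
                         frame_range = NULL) {
  stopifnot(inherits(seq, "bmode_sequence"))
  if (inherits(points, "point_set")) points <- points$points
  pts <- as.matrix(points)
  nfr <- dim(seq$frames)[3]
  if (is.null(frame_range)) frame_range <- seq_len(nfr)
  stopifnot(all(frame_range >= 1), all(frame_range <= nfr),
            length(frame_range) >= 2)
  dx <- seq$pixel_spacing[1]; dy <- seq$pixel_spacing[2]
  n <- nrow(pts)
  K <- length(frame_range)
  # pre-filter + pyramid for every needed frame, built once
  lev1 <- lapply(frame_range, function(k)
    cpp_gauss_blur(seq$frames[, , k], params$blur_sigma))
  pyr <- lapply(lev1, function(im) {
    out <- list(im)
    if (params$pyramid_levels >= 2)
      for (l in 2:params$pyramid_levels) out[[l]] <- pyr_down(out[[l - 1]])
    out
  })
  pos <- array(NA_real_, c(n, K, 2))
  pos[, 1, ] <- pts
  warned <- FALSE
  for (k in seq_len(K - 1)) {
    cur <- pos[, k, , drop = TRUE]
    if (n == 1) cur <- matrix(cur, 1, 2)
    inc <- pair_increment(pyr[[k]], pyr[[k + 1]],
                          cur[, 1] / dx, cur[, 2] / dy, params)
    if (inc$left && !warned) {
      warning("some points left the image; their displacement is frozen")
      warned <- TRUE
    }
    inc_mm <- cbind(inc$ux * dx, inc$uy * dy)
    inc_mm <- smooth_increments(cur, inc_mm, params$smooth_sigma_mm)
    pos[, k + 1, ] <- cur + inc_mm
  }
  disp <- pos
  for (j in 1:2) disp[, , j] <- pos[, , j] - pos[, 1, j]
  structure(list(positions = pos, displacements = disp,
                 frames = frame_range,
                 direction = if (frame_range[1] <= frame_range[K]) "forward" else "backward"),
            class = "track_result")
}

#' Merge forward and backward tracking passes
#'
#' The backward pass is re-indexed to the forward timeline and blended
#' linearly in time: at frame k of K (0-based), merged = w * forward +
#' (1 - w) * backward with w = 1 - k/(K-1), so the forward pass is trusted
#' near its seed frame and the backward pass near its own.
#'
#' @param fwd forward `track_result` over a cycle.
#' @param bwd backward `track_result` over the same cycle frame range,
#'   seeded at the last frame with the same point coordinates (the wall
#'   returns to its end-diastolic position at the cycle end).
#' @return merged `track_result` on the forward timeline.
#' @export
merge_forward_backward <- function(fwd, bwd) {
  stopifnot(inherits(fwd, "track_result"), inherits(bwd, "track_result"))
  n <- dim(fwd$positions)[1]
  K <- dim(fwd$positions)[2]
  if (dim(bwd$positions)[1] != n) stop("point counts differ between passes")
  if (dim(bwd$positions)[2] != K ||
      !all(rev(bwd$frames) == fwd$frames))
    stop("frame ranges of the two passes do not match")
  posb <- bwd$positions[, K:1, , drop = FALSE]  # re-index to forward timeline
  w <- 1 - (seq_len(K) - 1) / (K - 1)
  wa <- array(rep(w, each = n), c(n, K, 2))
  pos <- wa * fwd$positions + (1 - wa) * posb
  disp <- pos
  for (j in 1:2) disp[, , j] <- pos[, , j] - pos[, 1, j]
  structure(list(positions = pos, displacements = disp, frames = fwd$frames,
                 direction = "merged"),
            class = "track_result")
}

#' Track one pressure cycle forward and backward, merged
#'
#' Runs [track_points()] forward from the cycle start and backward from the
#' cycle end (each cycle is tracked independently), then merges the passes
#' with [merge_forward_backward()].
#'
#' @inheritParams track_points
#' @param start,end first and last frame index of the cycle.
#' @return merged `track_result`.
#' @export
track_cycle <- function(seq, points, params = tracking_params(),
                        start = 1L, end = dim(seq$frames)[3]) {
  fwd <- track_points(seq, points, params, frame_range = start:end)
  bwd <- track_points(seq, points, params, frame_range = end:start)
  merge_forward_backward(fwd, bwd)
}

#' @export
print.track_result <- function(x, ...) {
  d <- dim(x$positions)
  cat(sprintf("track_result (%s): %d points x %d frames [%d..%d]\n",
              x$direction, d[1], d[2], x$frames[1], x$frames[length(x$frames)]))
  invisible(x)
}

#' Export a track result as a long-format table
#'
#' @param track a `track_result`.
#' @return data frame `point_id, frame, x_mm, y_mm, ux_mm, uy_mm`.
#' @export
track_table <- function(track) {
  d <- dim(track$positions)
  data.frame(
    point_id = rep(seq_len(d[1]), d[2]),
    frame = rep(track$frames, each = d[1]),
    x_mm = as.vector(track$positions[, , 1]),
    y_mm = as.vector(track$positions[, , 2]),
    ux_mm = as.vector(track$displacements[, , 1]),
    uy_mm = as.vector(track$displacements[, , 2])
  )
}
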