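#' Antero-posterior diameter over time
#'
#' For each frame, the vertical line through the x-coordinate of the tracked
#' inner-contour centroid is intersected with the contour polyline; the AP
#' diameter is the vertical extent between the lowest and highest crossing.
#' The centroid is recomputed per frame, so the measuring line follows the
#' moving vessel.
#'
#' @param contour_track a `track_result` of the inner-wall contour points (or
#'   an `n x K x 2` array of positions in mm).
#' @param frame_rate frames per second, Hz.
#' @return object of class `diameter_series`: list with `values` (mm per
#'   frame), `times` (s), `frame_rate`.
#' @export
ap_diameter <- function(contour_track, frame_rate) {
  pos <- if (inherits(contour_track, "track_result")) contour_track$positions else contour_track
  stopifnot(length(dim(pos)) == 3, dim(pos)[3] == 2)
  K <- dim(pos)[2]
  vals <- vapply(seq_len(K), function(k) {
    x <- pos[, k, 1]; y <- pos[, k, 2]
    cx <- mean(x)
    n <- length(x)
    i2 <- c(2:n, 1)
    dxs <- x[i2] - x
    crossing <- (x - cx) * (x[i2] - cx) <= 0 & !(x == cx & x[i2] == cx)
    crossing <- crossing & abs(dxs) > 1e-12
    if (sum(crossing) < 2) stop("degenerate contour: fewer than 2 crossings of the AP line")
    t <- (cx - x[crossing]) / dxs[crossing]
    ys <- y[crossing] + t * (y[i2][crossing] - y[crossing])
    max(ys) - min(ys)
  }, numeric(1))
  structure(list(values = vals, times = (seq_len(K) - 1) / frame_rate,
                 frame_rate = frame_rate),
            class = "diameter_series")
}

#' @export
print.diameter_series <- function(x, ...) {
  cat(sprintf("diameter_series: %d frames, %.2f..%.2f mm\n",
              length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

# centered moving average, window w (edges use the available samples)
moving_average <- function(x, w = 3L) {
  n <- length(x)
  h <- w %/% 2
  vapply(seq_len(n), function(i)
    mean(x[max(1, i - h):min(n, i + h)]), numeric(1))
}

# Alternating local extrema of a series, endpoints included as candidates.
# Returns data.frame(index, type) with type +1 = maximum, -1 = minimum.
alternating_extrema <- function(s) {
  n <- length(s)
  d <- diff(s)
  sgn <- sign(d)
  # carry the sign over plateaus
  for (i in seq_along(sgn)) if (sgn[i] == 0 && i > 1) sgn[i] <- sgn[i - 1]
  idx <- integer(0); typ <- integer(0)
  # left endpoint
  first_sgn <- sgn[which(sgn != 0)[1]]
  if (!is.na(first_sgn)) {
    idx <- 1L; typ <- if (first_sgn > 0) -1L else 1L
  }
  for (i in seq_len(n - 2)) {
    if (sgn[i] != 0 && sgn[i + 1] != 0 && sgn[i] != sgn[i + 1]) {
      idx <- c(idx, i + 1L)
      typ <- c(typ, if (sgn[i] > 0) 1L else -1L)
    }
  }
  last_sgn <- sgn[rev(which(sgn != 0))[1]]
  if (!is.na(last_sgn)) {
    idx <- c(idx, n)
    typ <- c(typ, if (last_sgn > 0) 1L else -1L)
  }
  # collapse runs of equal type, keeping the most extreme representative
  keep_i <- integer(0); keep_t <- integer(0)
  for (k in seq_along(idx)) {
    if (length(keep_t) && typ[k] == keep_t[length(keep_t)]) {
      j <- length(keep_i)
      better <- if (typ[k] > 0) s[idx[k]] > s[keep_i[j]] else s[idx[k]] < s[keep_i[j]]
      if (better) keep_i[j] <- idx[k]
    } else {
      keep_i <- c(keep_i, idx[k]); keep_t <- c(keep_t, typ[k])
    }
  }
  data.frame(index = keep_i, type = keep_t)
}

#' Split a diameter series into pressure cycles
#'
#' The series is smoothed with a 3-frame moving average; alternating local
#' minima (end-diastole) and maxima (peak-systole) are detected, pruned by a
#' prominence filter (adjacent min-max amplitude at least `prominence_frac`
#' of the series peak-to-peak range) and a minimum peak separation
#' (`min_separation_s`). Each cycle spans one minimum to the next and
#' contains exactly one maximum; `delta_d` is the smoothed diameter increase
#' from cycle start to its peak. Cycle durations outside the physiological
#' plausibility window of 0.3 to 2.0 s are reported with a warning, not an
#' error.
#'
#' @param d a [ap_diameter()] result.
#' @param prominence_frac prominence threshold as a fraction of the series
#'   peak-to-peak range.
#' @param min_separation_s minimum time between successive systolic peaks, s.
#' @return object of class `cycle_set`: data frame `cycles` with columns
#'   `start_frame`, `peak_frame`, `end_frame`, `delta_d`; plus
#'   `reference_index` (`NA` until [select_reference_cycle()] is applied).
#'   Zero rows when no complete cycle is found.
#' @export
detect_cycles <- function(d, prominence_frac = 0.25, min_separation_s = 0.3) {
  stopifnot(inherits(d, "diameter_series"))
  s <- moving_average(d$values, 3L)
  ptp <- max(s) - min(s)
  empty <- structure(list(cycles = data.frame(start_frame = integer(0),
                                              peak_frame = integer(0),
                                              end_frame = integer(0),
                                              delta_d = numeric(0)),
                          reference_index = NA_integer_),
                     class = "cycle_set")
  if (ptp <= 0) return(empty)
  ext <- alternating_extrema(s)
  prom <- prominence_frac * ptp
  # iteratively remove the weakest adjacent extremum pair below the
  # prominence threshold, then re-collapse the alternation
  repeat {
    if (nrow(ext) < 2) break
    amp <- abs(diff(s[ext$index]))
    j <- which.min(amp)
    if (amp[j] >= prom) break
    ext <- ext[-c(j, j + 1), , drop = FALSE]
    # merge neighbors of equal type that became adjacent
    k <- 1
    while (k < nrow(ext)) {
      if (ext$type[k] == ext$type[k + 1]) {
        si <- c(ext$index[k], ext$index[k + 1])
        pick <- if (ext$type[k] > 0) which.max(s[si]) else which.min(s[si])
        ext$index[k] <- si[pick]
        ext <- ext[-(k + 1), , drop = FALSE]
      } else k <- k + 1
    }
  }
  # minimum separation between systolic peaks: drop the lower of two close peaks
  min_sep <- min_separation_s * d$frame_rate
  repeat {
    pk <- which(ext$type > 0)
    if (length(pk) < 2) break
    gaps <- diff(ext$index[pk])
    j <- which(gaps < min_sep)
    if (!length(j)) break
    j <- j[1]
    lo <- if (s[ext$index[pk[j]]] <= s[ext$index[pk[j + 1]]]) pk[j] else pk[j + 1]
    ext <- ext[-lo, , drop = FALSE]
    k <- 1
    while (k < nrow(ext)) {
      if (ext$type[k] == ext$type[k + 1]) {
        si <- c(ext$index[k], ext$index[k + 1])
        pick <- if (ext$type[k] > 0) which.max(s[si]) else which.min(s[si])
        ext$index[k] <- si[pick]
        ext <- ext[-(k + 1), , drop = FALSE]
      } else k <- k + 1
    }
  }
  mins <- ext$index[ext$type < 0]
  maxs <- ext$index[ext$type > 0]
  if (length(mins) < 2 || length(maxs) < 1) return(empty)
  rows <- list()
  for (i in seq_len(length(mins) - 1)) {
    inside <- maxs[maxs > mins[i] & maxs < mins[i + 1]]
    if (length(inside) != 1) next
    rows[[length(rows) + 1]] <- data.frame(
      start_frame = mins[i], peak_frame = inside, end_frame = mins[i + 1],
      delta_d = s[inside] - s[mins[i]])
  }
  if (!length(rows)) return(empty)
  cyc <- do.call(rbind, rows)
  dur <- (cyc$end_frame - cyc$start_frame) / d$frame_rate
  if (any(dur < 0.3 | dur > 2.0))
    warning(sprintf("%d cycle(s) with implausible duration outside [0.3, 2.0] s",
                    sum(dur < 0.3 | dur > 2.0)))
  structure(list(cycles = cyc, reference_index = NA_integer_),
            class = "cycle_set")
}

#' @export
print.cycle_set <- function(x, ...) {
  cat(sprintf("cycle_set: %d cycle(s)", nrow(x$cycles)))
  if (!is.na(x$reference_index)) cat(sprintf(", reference = %d", x$reference_index))
  cat("\n")
  if (nrow(x$cycles)) print(x$cycles)
  invisible(x)
}

#' Select the reference cycle
#'
#' The reference is the cycle whose systolic diameter increase `delta_d` is
#' closest to the mean `delta_d` over all cycles; ties go to the earliest
#' cycle.
#'
#' @param cycles a [detect_cycles()] result.
#' @return the `cycle_set` with `reference_index` set.
#' @export
select_reference_cycle <- function(cycles) {
  stopifnot(inherits(cycles, "cycle_set"))
  if (nrow(cycles$cycles) == 0) stop("no cycles to select a reference from")
  dev <- abs(cycles$cycles$delta_d - mean(cycles$cycles$delta_d))
  cycles$reference_index <- which.min(dev)  # which.min takes the earliest tie
  cycles
}
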