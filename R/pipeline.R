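#' Run the full strain-mapping pipeline on a sequence
#'
#' End-to-end analysis of a B-mode cine-loop: resample the manual landmarks,
#' build the wall grid, track the inner contour over the (optionally
#' cropped) sequence to measure the antero-posterior diameter, detect
#' pressure cycles and the reference cycle, select high-gradient tracking
#' points on the first frame of the first analyzed cycle, track each cycle
#' forward and backward (merged), and map strains per cycle on the grid.
#' All stage outputs and a JSON run report (cycle count, per-cycle diameter
#' increase, per-stage timing) are written when `out_dir` is given.
#'
#' @param seq a [bmode_sequence()].
#' @param landmarks a [wall_contour()] of manual inner-wall landmarks (or a
#'   path readable by [read_landmarks()]).
#' @param config a [default_config()]-style list; `config$frames = c(a, b)`
#'   crops the analysis to that frame range.
#' @param out_dir optional output directory for CSV/JSON exports.
#' @return list with `grid`, `diameters`, `cycles`, `points`, `tracks`
#'   (one merged `track_result` per cycle), `strains` (one
#'   `strain_field_set` per cycle), `report`.
#' @export
run_pipeline <- function(seq, landmarks, config = default_config(),
                         out_dir = NULL) {
  stopifnot(inherits(seq, "bmode_sequence"))
  if (is.character(landmarks)) landmarks <- read_landmarks(landmarks)
  tp <- do.call(tracking_params, config$tracking)
  timing <- list()
  tic <- function() proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t0 <- tic()
    r <- tryCatch(force(expr),
                  error = function(e) stop(sprintf("[%s] %s", name, conditionMessage(e)),
                                           call. = FALSE))
    timing[[name]] <<- tic() - t0
    r
  }
  nfr <- dim(seq$frames)[3]
  crop <- if (!is.null(config$frames)) config$frames else c(1L, nfr)
  stopifnot(crop[1] >= 1, crop[2] <= nfr, crop[1] < crop[2])

  contour <- stage("resample_contour",
                   resample_contour(landmarks, config$contour_points))
  grid <- stage("build_wall_grid",
                build_wall_grid(contour, thickness = config$thickness_mm,
                                n_layers = config$n_layers))
  ctrack <- stage("track_contour",
                  track_points(seq, contour$points, tp,
                               frame_range = crop[1]:crop[2]))
  dia <- stage("ap_diameter", ap_diameter(ctrack, seq$frame_rate))
  cycles <- stage("detect_cycles",
                  detect_cycles(dia, config$prominence_frac,
                                config$min_separation_s))
  if (nrow(cycles$cycles) == 0)
    stop("[detect_cycles] no complete pressure cycle found; crop or re-acquire",
         call. = FALSE)
  cycles <- select_reference_cycle(cycles)
  # cycle frames are indices into the cropped range; map back to the sequence
  cyc <- cycles$cycles
  cyc$start_frame <- cyc$start_frame + crop[1] - 1L
  cyc$peak_frame <- cyc$peak_frame + crop[1] - 1L
  cyc$end_frame <- cyc$end_frame + crop[1] - 1L
  first_frame <- cyc$start_frame[1]
  pts <- stage("select_points", {
    gradm <- sobel_gradient(seq$frames[, , first_frame])
    select_points(gradm, grid, seq$pixel_spacing,
                  min_dist = config$min_dist_mm)
  })
  tracks <- vector("list", nrow(cyc))
  strains <- vector("list", nrow(cyc))
  for (i in seq_len(nrow(cyc))) {
    tracks[[i]] <- stage(sprintf("track_cycle_%d", i),
                         track_cycle(seq, pts, tp,
                                     start = cyc$start_frame[i],
                                     end = cyc$end_frame[i]))
    strains[[i]] <- stage(sprintf("map_strains_%d", i),
                          map_strains(tracks[[i]], grid))
  }
  report <- list(n_frames = nfr, frames_analyzed = crop,
                 n_cycles = nrow(cyc), delta_d_mm = cyc$delta_d,
                 reference_cycle = cycles$reference_index,
                 n_tracking_points = nrow(pts$points),
                 timing_s = timing)
  res <- list(grid = grid, contour = contour, diameters = dia,
              cycles = cycles, cycle_frames = cyc, points = pts,
              tracks = tracks, strains = strains, report = report)
  if (!is.null(out_dir)) export_pipeline(res, out_dir)
  res
}

export_pipeline <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(res$grid),
                   file.path(out_dir, "wall_grid.csv"), row.names = FALSE)
  utils::write.csv(data.frame(frame = seq_along(res$diameters$values),
                              time_s = res$diameters$times,
                              diameter_mm = res$diameters$values),
                   file.path(out_dir, "ap_diameter.csv"), row.names = FALSE)
  jsonlite::write_json(list(cycles = res$cycle_frames,
                            reference_index = res$cycles$reference_index),
                       file.path(out_dir, "cycles.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  utils::write.csv(data.frame(x_mm = res$points$points[, 1],
                              y_mm = res$points$points[, 2],
                              score = res$points$scores),
                   file.path(out_dir, "tracking_points.csv"), row.names = FALSE)
  for (i in seq_along(res$tracks)) {
    utils::write.csv(track_table(res$tracks[[i]]),
                     file.path(out_dir, sprintf("track_cycle%02d.csv", i)),
                     row.names = FALSE)
    utils::write.csv(strain_table(res$strains[[i]]),
                     file.path(out_dir, sprintf("strain_cycle%02d.csv", i)),
                     row.names = FALSE)
  }
  jsonlite::write_json(res$report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
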