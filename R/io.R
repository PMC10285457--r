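#' Read a B-mode cine-loop from multi-frame TIFF + JSON sidecar
#'
#' The sidecar (`<stem>.json` next to the TIFF unless given) must contain
#' `pixel_spacing_mm` (length 2, mm/px) and `frame_rate_hz`.
#'
#' @param tiff_path multi-frame grayscale TIFF, 8-bit.
#' @param sidecar_path optional explicit sidecar path.
#' @return a [bmode_sequence()].
#' @export
read_bmode <- function(tiff_path, sidecar_path = NULL) {
  if (is.null(sidecar_path))
    sidecar_path <- paste0(sub("\\.tiff?$", "", tiff_path), ".json")
  meta <- jsonlite::fromJSON(sidecar_path)
  fr <- tiff::readTIFF(tiff_path, all = TRUE)
  if (!is.list(fr)) fr <- list(fr)
  frames <- array(NA_real_, c(nrow(fr[[1]]), ncol(fr[[1]]), length(fr)))
  for (k in seq_along(fr)) {
    f <- fr[[k]]
    if (length(dim(f)) == 3) f <- f[, , 1]      # grayscale stored as RGB
    frames[, , k] <- round(f * 255)
  }
  bmode_sequence(frames, as.numeric(meta$pixel_spacing_mm),
                 as.numeric(meta$frame_rate_hz))
}

#' Write a B-mode cine-loop as multi-frame TIFF + JSON sidecar
#'
#' @param seq a [bmode_sequence()].
#' @param tiff_path output TIFF path; the sidecar goes to `<stem>.json`.
#' @return `tiff_path`, invisibly.
#' @export
write_bmode <- function(seq, tiff_path) {
  stopifnot(inherits(seq, "bmode_sequence"))
  K <- dim(seq$frames)[3]
  fr <- lapply(seq_len(K), function(k) seq$frames[, , k] / 255)
  tiff::writeTIFF(fr, tiff_path, bits.per.sample = 8, compression = "none")
  jsonlite::write_json(
    list(pixel_spacing_mm = seq$pixel_spacing, frame_rate_hz = seq$frame_rate),
    paste0(sub("\\.tiff?$", "", tiff_path), ".json"),
    auto_unbox = TRUE, digits = NA)
  invisible(tiff_path)
}

#' Read inner-wall landmarks
#'
#' Accepts a CSV with header `x_mm,y_mm` or a JSON file holding either a
#' list of `[x, y]` pairs or an object with `x_mm`/`y_mm` arrays.
#'
#' @param path landmark file.
#' @return a [wall_contour()].
#' @export
read_landmarks <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    j <- jsonlite::fromJSON(path)
    pts <- if (is.list(j) && !is.null(j$x_mm)) cbind(j$x_mm, j$y_mm) else as.matrix(j)
  } else {
    d <- utils::read.csv(path)
    pts <- cbind(d$x_mm, d$y_mm)
  }
  wall_contour(pts)
}

#' Write inner-wall landmarks as CSV
#'
#' @param contour a [wall_contour()].
#' @param path output CSV path (header `x_mm,y_mm`).
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(contour, path) {
  utils::write.csv(data.frame(x_mm = contour$points[, 1],
                              y_mm = contour$points[, 2]),
                   path, row.names = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' All tunable parameters of the pipeline in one serializable list:
#' geometry (wall thickness, layers), point selection (minimum distance),
#' tracking ([tracking_params()] fields), cycle detection (prominence, peak
#' separation), phantom defaults and the RNG seed. Written to / read from a
#' single YAML file; unknown keys are rejected.
#'
#' @return named list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(list(
    thickness_mm = 2.0,
    n_layers = 4L,
    min_dist_mm = 1.0,
    contour_points = 48L,
    tracking = unclass(tracking_params()),
    prominence_frac = 0.25,
    min_separation_s = 0.3,
    frames = NULL,
    phantom = list(lumen_radius_mm = 10, peak_inner_displacement_mm = 0.5,
                   n_frames = 33L, n_scatterers = 11000L,
                   pixel_spacing_mm = c(0.22, 0.22)),
    seed = 1L
  ), class = "pipeline_config")
}

#' Read / write a pipeline configuration
#'
#' @param path YAML file.
#' @return [read_config()]: a `pipeline_config` (defaults filled in);
#'   [write_config()]: `path`, invisibly.
#' @export
read_config <- function(path) {
  cfg <- default_config()
  y <- yaml::read_yaml(path)
  unknown <- setdiff(names(y), names(cfg))
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  for (k in names(y)) {
    if (is.list(cfg[[k]]) && is.list(y[[k]])) {
      cfg[[k]][names(y[[k]])] <- y[[k]]
    } else {
      cfg[[k]] <- y[[k]]
    }
  }
  cfg
}

#' @rdname read_config
#' @param config a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
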