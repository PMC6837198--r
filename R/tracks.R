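# Reading per-second chamber tracks and compass headings, converting head
# positions to magnetic bearings in the rotating chamber frame, and computing
# swimming speed. The system boundary is the post-tracking interface: positions
# in camera pixels plus the digital-compass heading of the camera's up-axis.
#
# Track file dialect: optional "# key: value" comment lines, then a header
# "t_s,x_px,y_px", one row per second. Compass files: "t_s,heading_deg".
# The y-axis convention of the position file is recorded in its header
# ("# y_axis: up" or "down"); bearing math assumes mathematical y-up and the
# conversion (about the calibrated centre) happens in bearings_from_track().

#' Chamber calibration
#'
#' @param center_x,center_y arena centre in camera pixels.
#' @param radius_px arena radius in pixels.
#' @param radius_cm arena radius in cm; default 20 (a 40 cm diameter arena).
#' @return a `chamber_calibration` list.
#' @export
chamber_calibration <- function(center_x, center_y, radius_px, radius_cm = 20) {
  stopifnot(is.finite(center_x), is.finite(center_y),
            is.finite(radius_px), is.finite(radius_cm))
  if (radius_px <= 0 || radius_cm <= 0) stop("degenerate calibration")
  structure(list(center_x = center_x, center_y = center_y,
                 radius_px = radius_px, radius_cm = radius_cm),
            class = "chamber_calibration")
}

#' Deployment metadata
#'
#' @param id deployment identifier.
#' @param utc_start deployment start (POSIXct or ISO string, UTC).
#' @param latitude,longitude site coordinates, degrees.
#' @param tide_phase `"ebb"` or `"flood"`; always supplied, never inferred.
#' @param site_name free-text site label.
#' @param acclimation_s acclimation window discarded at the start, seconds
#'   (default 300 = 5 min).
#' @param analysis_s analysed window after acclimation, seconds
#'   (default 600 = 10 min at 1 Hz).
#' @return a `deployment_meta` list.
#' @export
deployment_meta <- function(id, utc_start, latitude, longitude, tide_phase,
                            site_name = "", acclimation_s = 300,
                            analysis_s = 600) {
  if (missing(tide_phase) || is.null(tide_phase) || is.na(tide_phase)) {
    stop("tide_phase is required metadata (ebb or flood)")
  }
  tide_phase <- match.arg(tide_phase, c("ebb", "flood"))
  structure(list(id = as.character(id), utc_start = as_utc(utc_start),
                 latitude = latitude, longitude = longitude,
                 tide_phase = tide_phase, site_name = site_name,
                 acclimation_s = acclimation_s, analysis_s = analysis_s),
            class = "deployment_meta")
}

read_dialect <- function(path, required, what) {
  if (!file.exists(path)) stop(sprintf("%s file not found: %s", what, path))
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  meta <- list()
  for (l in lines[hdr]) {
    kv <- regmatches(l, regexec("^#\\s*([A-Za-z_0-9]+)\\s*:\\s*(.*)$", l))[[1]]
    if (length(kv) == 3) meta[[kv[2]]] <- trimws(kv[3])
  }
  body <- which(!hdr)
  if (!length(body)) stop(sprintf("%s file %s: no header row", what, path))
  cols <- strsplit(trimws(lines[body[1]]), ",")[[1]]
  missing_cols <- setdiff(required, cols)
  if (length(missing_cols)) {
    stop(sprintf("%s file %s: missing required columns: %s", what, path,
                 paste(missing_cols, collapse = ", ")))
  }
  data_lines <- body[-1]
  rows <- strsplit(lines[data_lines], ",")
  bad <- which(lengths(rows) != length(cols))
  if (length(bad)) {
    stop(sprintf("%s file %s: malformed rows at lines %s", what, path,
                 paste(data_lines[bad], collapse = ", ")))
  }
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- cols
  for (cc in required) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    nb <- which(!is.finite(v))
    if (length(nb)) {
      stop(sprintf("%s file %s: non-numeric '%s' at lines %s", what, path, cc,
                   paste(data_lines[nb], collapse = ", ")))
    }
    df[[cc]] <- v
  }
  dup <- which(duplicated(df$t_s))
  if (length(dup)) {
    stop(sprintf("%s file %s: duplicated timestamp at line %d", what, path,
                 data_lines[dup[1]]))
  }
  df <- df[order(df$t_s), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "file_meta") <- meta
  df
}

#' Read a per-second trajectory file
#'
#' @param path track file (`t_s,x_px,y_px` dialect).
#' @param id deployment identifier attached to the track.
#' @return a `track` data.frame with columns `t_s, x_px, y_px`, attributes
#'   `id` and `y_axis` (`"up"` or `"down"`, default `"up"`), sorted by `t_s`.
#'   Missing seconds are left as gaps (never interpolated).
#' @export
read_track <- function(path, id = tools::file_path_sans_ext(basename(path))) {
  df <- read_dialect(path, c("t_s", "x_px", "y_px"), "track")
  y_axis <- attr(df, "file_meta")$y_axis
  if (is.null(y_axis)) y_axis <- "up"
  y_axis <- match.arg(y_axis, c("up", "down"))
  structure(df, id = as.character(id), y_axis = y_axis,
            class = c("track", "data.frame"))
}

#' Read a compass-heading file
#'
#' @param path compass file (`t_s,heading_deg` dialect); headings are the
#'   magnetic heading of the camera's up-axis, wrapped into \[0, 360).
#' @return a `compass_series` data.frame sorted by `t_s`.
#' @export
read_compass <- function(path) {
  df <- read_dialect(path, c("t_s", "heading_deg"), "compass")
  df$heading_deg <- wrap_degrees(df$heading_deg)
  structure(df, class = c("compass_series", "data.frame"))
}

#' Write a track / compass file in the package dialect
#'
#' @param x a `track` or `compass_series` data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_track <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# y_axis: %s", attr(x, "y_axis") %||% "up"), con)
  writeLines("t_s,x_px,y_px", con)
  writeLines(sprintf("%d,%.6f,%.6f", as.integer(x$t_s), x$x_px, x$y_px), con)
  invisible(path)
}

#' @rdname write_track
#' @export
write_compass <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("t_s,heading_deg", con)
  writeLines(sprintf("%d,%.6f", as.integer(x$t_s), x$heading_deg), con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write a flat key-value deployment metadata file
#'
#' One `key = value` pair per line: `id, utc_start, lat, lon, tide_phase,
#' site, center_x, center_y, radius_px, radius_cm` (optionally
#' `acclimation_s, analysis_s`).
#'
#' @param path metadata file.
#' @return `read_deployment_meta()`: a list with elements `meta`
#'   ([deployment_meta]) and `cal` ([chamber_calibration]).
#' @export
read_deployment_meta <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  lines <- grep("^\\s*(#|$)", readLines(path), invert = TRUE, value = TRUE)
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- which(lengths(kv) != 2)
  if (length(bad)) stop("metadata file ", path, ": malformed line ", bad[1])
  vals <- trimws(vapply(kv, `[`, "", 2))
  names(vals) <- trimws(vapply(kv, `[`, "", 1))
  req <- c("id", "utc_start", "lat", "lon", "tide_phase", "site",
           "center_x", "center_y", "radius_px", "radius_cm")
  miss <- setdiff(req, names(vals))
  if (length(miss)) {
    stop("metadata file ", path, ": missing keys: ", paste(miss, collapse = ", "))
  }
  num <- function(k, default = NULL) {
    if (!k %in% names(vals)) return(default)
    as.numeric(vals[[k]])
  }
  list(meta = deployment_meta(vals[["id"]], vals[["utc_start"]],
                              num("lat"), num("lon"), vals[["tide_phase"]],
                              vals[["site"]],
                              acclimation_s = num("acclimation_s", 300),
                              analysis_s = num("analysis_s", 600)),
       cal = chamber_calibration(num("center_x"), num("center_y"),
                                 num("radius_px"), num("radius_cm")))
}

#' @rdname read_deployment_meta
#' @param meta a [deployment_meta].
#' @param cal a [chamber_calibration].
#' @export
write_deployment_meta <- function(meta, cal, path) {
  lines <- c(
    sprintf("id = %s", meta$id),
    sprintf("utc_start = %s", format(meta$utc_start, "%Y-%m-%dT%H:%M:%S")),
    sprintf("lat = %.6f", meta$latitude),
    sprintf("lon = %.6f", meta$longitude),
    sprintf("tide_phase = %s", meta$tide_phase),
    sprintf("site = %s", meta$site_name),
    sprintf("acclimation_s = %d", as.integer(meta$acclimation_s)),
    sprintf("analysis_s = %d", as.integer(meta$analysis_s)),
    sprintf("center_x = %.6f", cal$center_x),
    sprintf("center_y = %.6f", cal$center_y),
    sprintf("radius_px = %.6f", cal$radius_px),
    sprintf("radius_cm = %.6f", cal$radius_cm))
  writeLines(lines, path)
  invisible(path)
}

# Seconds retained for analysis: [acclimation_s, acclimation_s + analysis_s),
# truncated (with a warning) if the track ends earlier.
analysis_window <- function(track, meta) {
  lo <- meta$acclimation_s
  hi <- meta$acclimation_s + meta$analysis_s
  if (max(track$t_s) + 1 < hi) {
    warning(sprintf("track %s shorter than acclimation + analysis window; truncating",
                    attr(track, "id") %||% "?"))
  }
  track$t_s >= lo & track$t_s < hi
}

#' Magnetic bearings from a chamber track
#'
#' For each retained second in the analysis window, the camera-frame angle of
#' the head position about the calibrated centre (0 = image-up, clockwise
#' positive) is rotated into the magnetic frame by the compass heading of the
#' camera's up-axis, matched by nearest timestamp within 1 s:
#' `bearing = wrap(theta_cam + heading)`. This exactly cancels chamber
#' rotation. Positions outside the arena circle plus 5% slack are dropped
#' (counted as gaps) with a warning. If more than 10% of retained seconds
#' have no compass match the deployment is unusable and an error is raised.
#' If fewer than 80% of the nominal analysis seconds survive, the result
#' carries `attr(, "low_coverage") = TRUE`.
#'
#' @param track a [read_track()] data.frame.
#' @param compass a [read_compass()] data.frame.
#' @param cal a [chamber_calibration].
#' @param meta a [deployment_meta].
#' @return an [angle_series] (frame `magnetic_north`) with attributes
#'   `t_s`, `coverage` and `low_coverage`.
#' @export
bearings_from_track <- function(track, compass, cal, meta) {
  keep <- analysis_window(track, meta)
  tr <- track[keep, , drop = FALSE]
  if (!nrow(tr)) stop("no samples in the analysis window")
  dx <- tr$x_px - cal$center_x
  dy <- tr$y_px - cal$center_y
  if (identical(attr(track, "y_axis"), "down")) dy <- -dy
  rr <- sqrt(dx^2 + dy^2)
  inside <- rr <= cal$radius_px * 1.05
  if (any(!inside)) {
    warning(sprintf("%d position(s) outside the arena circle (+5%% slack); dropped",
                    sum(!inside)))
    tr <- tr[inside, , drop = FALSE]; dx <- dx[inside]; dy <- dy[inside]
  }
  if (!nrow(tr)) stop("no samples in the analysis window")
  theta_cam <- wrap_degrees(rad2deg(atan2(dx, dy)))  # 0 = image-up, clockwise
  idx <- findInterval(tr$t_s, compass$t_s, all.inside = FALSE)
  idx[idx == 0] <- 1L
  idx_hi <- pmin(idx + 1L, nrow(compass))
  use_hi <- abs(compass$t_s[idx_hi] - tr$t_s) < abs(compass$t_s[idx] - tr$t_s)
  idx[use_hi] <- idx_hi[use_hi]
  matched <- abs(compass$t_s[idx] - tr$t_s) <= 1
  if (mean(matched) < 0.9) stop("compass coverage: >10% of samples unmatched within 1 s")
  theta_cam <- theta_cam[matched]
  tr <- tr[matched, , drop = FALSE]
  bearings <- wrap_degrees(theta_cam + compass$heading_deg[idx[matched]])
  out <- angle_series(bearings, frame = "magnetic_north")
  coverage <- nrow(tr) / meta$analysis_s
  attr(out, "t_s") <- tr$t_s
  attr(out, "coverage") <- coverage
  attr(out, "low_coverage") <- coverage < 0.8
  out
}

#' Swimming speed from a chamber track
#'
#' Euclidean step length between consecutive retained seconds, scaled from
#' pixels to cm by the calibration, per 1 s step. Steps spanning gaps
#' (dt != 1 s) are excluded rather than averaged over.
#'
#' @inheritParams bearings_from_track
#' @return a list with `per_second` (cm s^-1, one per valid step), `mean`
#'   and `median`.
#' @export
swimming_speed <- function(track, cal, meta) {
  if (cal$radius_px <= 0 || cal$radius_cm <= 0) stop("degenerate calibration")
  keep <- analysis_window(track, meta)
  tr <- track[keep, , drop = FALSE]
  if (nrow(tr) < 2) stop("swimming_speed: need at least 2 retained samples")
  dt <- diff(tr$t_s)
  step_px <- sqrt(diff(tr$x_px)^2 + diff(tr$y_px)^2)
  v <- step_px[dt == 1] * (cal$radius_cm / cal$radius_px)
  if (!length(v)) stop("swimming_speed: no consecutive-second steps")
  list(per_second = v, mean = mean(v), median = stats::median(v))
}
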