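#' Frames of reference for bearing series
#'
#' Bearings are always stored in degrees in \[0, 360), 0 = north of the frame,
#' clockwise positive. `magnetic_north` is the native frame of compass-corrected
#' chamber tracks; `moon_relative` / `sun_relative` hold bearings re-expressed
#' against the body's azimuth (0 = toward the cue, 180 = away); `camera` is the
#' raw chamber frame (0 = image-up) before compass correction.
#'
#' @export
BEARING_FRAMES <- c("magnetic_north", "true_north", "moon_relative",
                    "sun_relative", "camera")

#' Wrap angles into \[0, 360)
#'
#' Single shared wrapping utility: all public functions that return degrees go
#' through this.
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector in \[0, 360).
#' @export
wrap_degrees <- function(x) {
  out <- x %% 360
  # -1e-15 %% 360 == 360 in floating point; force the right-open interval
  out[out >= 360] <- 0
  out
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Clockwise angular difference between two bearings
#'
#' `angular_difference(a, b)` is `a - b` wrapped into \[0, 360). With `a` an
#' animal's mean bearing and `b` a cue azimuth (e.g. the moon), 0 means
#' "toward the cue" and 180 "away from the cue".
#'
#' @param a,b bearings in degrees (vectorised, recycled).
#' @return degrees in \[0, 360).
#' @export
angular_difference <- function(a, b) {
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    stop("angular_difference: non-finite input")
  }
  wrap_degrees(a - b)
}

#' Signed smallest rotation from `b` to `a`, in (-180, 180]
#'
#' Convenience for coverage checks and confidence arcs.
#' @param a,b bearings in degrees.
#' @return signed degrees in (-180, 180].
#' @export
angular_deviation <- function(a, b) {
  d <- wrap_degrees(a - b)
  ifelse(d > 180, d - 360, d)
}

#' Construct a validated bearing series
#'
#' @param angles numeric vector of bearings in degrees; wrapped into \[0, 360).
#' @param frame one of [BEARING_FRAMES].
#' @return an object of class `angle_series`: the wrapped numeric vector with
#'   attributes `frame` and `n`.
#' @export
angle_series <- function(angles, frame = "magnetic_north") {
  frame <- match.arg(frame, BEARING_FRAMES)
  if (length(angles) < 1L) stop("no samples")
  if (!is.numeric(angles) || !all(is.finite(angles))) {
    stop("angle_series: angles must be finite numeric")
  }
  structure(wrap_degrees(as.numeric(angles)),
            frame = frame, n = length(angles), class = "angle_series")
}

as_angle_series <- function(x, frame = "magnetic_north") {
  if (inherits(x, "angle_series")) x else angle_series(x, frame)
}

series_frame <- function(x) {
  f <- attr(x, "frame")
  if (is.null(f)) "magnetic_north" else f
}

#' @export
print.angle_series <- function(x, ...) {
  cat(sprintf("<angle_series> n=%d frame=%s\n", length(x), series_frame(x)))
  print(as.numeric(x), ...)
  invisible(x)
}
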