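# Shared fixtures, all built in code.

default_cal <- function() chamber_calibration(512, 512, 400, 20)

default_meta <- function(id = "dep1", utc = "2015-04-19 10:00:00",
                         lat = 60.09, lon = 5.28, tide = "ebb", ...) {
  deployment_meta(id, utc, lat, lon, tide, site_name = "Langenuen", ...)
}

# A track whose head sits at fixed camera angles (deg, 0 = image-up,
# clockwise) at fixed radius; y-up dialect.
track_at_angles <- function(theta_cam, cal = default_cal(), radius_frac = 0.5,
                            t_s = seq_along(theta_cam) - 1L, id = "t") {
  r <- radius_frac * cal$radius_px
  structure(data.frame(t_s = t_s,
                       x_px = cal$center_x + r * sin(theta_cam * pi / 180),
                       y_px = cal$center_y + r * cos(theta_cam * pi / 180)),
            id = id, y_axis = "up", class = c("track", "data.frame"))
}

flat_compass <- function(t_s, heading = 0) {
  structure(data.frame(t_s = t_s, heading_deg = rep(heading, length(t_s))),
            class = c("compass_series", "data.frame"))
}

# Minimal individual_result for pipeline-level unit tests that do not need
# track extraction.
fake_individual <- function(id, mean_bearing, rbar, p, alpha_moon,
                            mean_speed = 3, moon_phase = "new",
                            tide_phase = "ebb", above = TRUE,
                            excluded = FALSE) {
  structure(list(
    id = id,
    magnetic = structure(list(mean_bearing = mean_bearing,
                              resultant_length = rbar, rayleigh_z = NA_real_,
                              p_value = p, n = 600,
                              ci95_lower = NA_real_, ci95_upper = NA_real_,
                              frame = "magnetic_north"),
                         class = "circular_summary"),
    moon_relative_bearing = alpha_moon,
    sun_relative_bearing = NA_real_,
    significant = p < 0.05,
    mean_speed = mean_speed, median_speed = mean_speed,
    conditions = list(moon_phase = moon_phase, tide_phase = tide_phase,
                      moon_above_horizon = above),
    coverage = 1, excluded = excluded,
    exclusion_reason = NA_character_), class = "individual_result")
}

# Frozen almanac oracle: topocentric (moon) / geocentric (sun) azimuth and
# altitude at Austevoll (60.09 N, 5.28 E, sea level, no refraction), computed
# once with a rigorous independent ephemeris (ERFA-based, arcsecond-class)
# and hard-coded here.
oracle_instants <- c(
  "2015-04-17 10:00:00", "2015-04-18 12:00:00", "2015-04-19 15:00:00",
  "2015-04-21 09:00:00", "2016-01-05 18:00:00", "2016-07-20 03:00:00",
  "2017-04-11 12:00:00", "2017-04-27 12:00:00", "2017-05-03 14:00:00",
  "2017-12-03 21:00:00")
oracle_moon <- matrix(c(
  171.8491, 32.1754, 190.9338, 36.8529, 227.7024, 33.7546,
  94.2445, 21.1645, 318.8655, -39.4144, 224.9117, 3.3405,
  1.1626, -36.3891, 167.5763, 41.9524, 105.5266, 24.0447,
  126.7171, 38.0384), ncol = 2, byrow = TRUE,
  dimnames = list(NULL, c("az", "alt")))
oracle_sun <- matrix(c(
  149.0882, 37.0615, 187.0235, 40.5529, 239.5940, 28.6565,
  131.6835, 33.6637, 261.5743, -21.4139, 44.6812, -0.1907,
  186.3484, 38.2571, 187.9038, 43.6891, 226.4755, 38.6273,
  308.8105, -44.0482), ncol = 2, byrow = TRUE,
  dimnames = list(NULL, c("az", "alt")))

# Full-enumeration oracle for the exact rank-sum branch: distribution of the
# group-a rank sum over all choose(N, n1) assignments of the pooled mid-ranks.
ranksum_enum_oracle <- function(a, b) {
  n1 <- length(a)
  rk <- rank(c(a, b))
  W <- sum(rk[seq_len(n1)])
  sums <- combn(length(rk), n1, function(ix) sum(rk[ix]))
  eps <- 1e-9
  lo <- mean(sums <= W + eps)
  hi <- mean(sums >= W - eps)
  min(1, 2 * min(lo, hi))
}
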