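# Self-contained low-precision ephemeris: topocentric moon and geocentric sun
# azimuth/altitude, lunar illuminated fraction and phase label. Truncated
# trigonometric series (main periodic terms of the standard lunar theory and a
# low-precision solar longitude), good to well under 1 degree for the moon and
# 0.01 degree for the sun over 1950-2050 -- far tighter than the tens-of-degrees
# scale of the orientation effects analysed downstream. No atmospheric
# refraction. TT - UTC is fixed at 69 s (documented constant, exact to a few
# seconds over the supported window, i.e. < 0.01 deg of lunar motion).

DELTA_T_S <- 69

#' Observation site
#'
#' @param latitude degrees north, |latitude| <= 90.
#' @param longitude degrees east; wrapped into (-180, 180].
#' @param magnetic_declination degrees, east positive. Added when converting
#'   true-north azimuths to the magnetic frame in which compass-corrected
#'   bearings live (magnetic azimuth = true azimuth - declination). Default 0:
#'   at the western-Norway sites this package was built around, declination in
#'   2015-2017 was about 0-1 degrees, below the precision of the analysis.
#' @return a `site` list.
#' @export
site <- function(latitude, longitude, magnetic_declination = 0) {
  stopifnot(is.finite(latitude), abs(latitude) <= 90,
            is.finite(longitude), is.finite(magnetic_declination))
  lon <- ((longitude + 180) %% 360) - 180
  if (lon == -180) lon <- 180
  structure(list(latitude = latitude, longitude = lon,
                 magnetic_declination = magnetic_declination),
            class = "site")
}

as_utc <- function(utc) {
  if (is.character(utc)) {
    out <- as.POSIXct(utc, tz = "UTC",
                      tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                     "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M",
                                     "%Y-%m-%d"))
  } else {
    out <- as.POSIXct(utc, tz = "UTC")
  }
  if (any(is.na(out))) stop("unparseable UTC datetime")
  out
}

check_window <- function(utc) {
  yr <- as.integer(format(utc, "%Y"))
  if (any(yr < 1950 | yr > 2050)) stop("ephemeris validity: date outside 1950-2050")
  utc
}

julian_day <- function(utc) as.numeric(utc) / 86400 + 2440587.5

# --- solar position (low-precision series, ~0.01 deg) -----------------------

sun_ecliptic <- function(T) {
  L0 <- 280.46646 + 36000.76983 * T + 0.0003032 * T^2
  M  <- 357.52911 + 35999.05029 * T - 0.0001537 * T^2
  Mr <- deg2rad(M)
  C <- (1.914602 - 0.004817 * T - 0.000014 * T^2) * sin(Mr) +
       (0.019993 - 0.000101 * T) * sin(2 * Mr) +
       0.000289 * sin(3 * Mr)
  true_lon <- L0 + C
  omega <- 125.04 - 1934.136 * T
  lambda <- true_lon - 0.00569 - 0.00478 * sin(deg2rad(omega))  # apparent
  list(lambda = wrap_degrees(lambda), beta = 0, M = M, L0 = L0)
}

mean_obliquity <- function(T) 23.43929111 - 0.01300417 * T - 1.638889e-7 * T^2

# --- lunar position (truncated main-term series) -----------------------------

# Periodic terms: multiples of (D, M, Mp, F); sl in 1e-6 deg, sr in 1e-3 km.
MOON_LR <- matrix(c(
  0, 0, 1, 0,  6288774, -20905355,
  2, 0,-1, 0,  1274027,  -3699111,
  2, 0, 0, 0,   658314,  -2955968,
  0, 0, 2, 0,   213618,   -569925,
  0, 1, 0, 0,  -185116,     48888,
  0, 0, 0, 2,  -114332,     -3149,
  2, 0,-2, 0,    58793,    246158,
  2,-1,-1, 0,    57066,   -152138,
  2, 0, 1, 0,    53322,   -170733,
  2,-1, 0, 0,    45758,   -204586,
  0, 1,-1, 0,   -40923,   -129620,
  1, 0, 0, 0,   -34720,    108743,
  0, 1, 1, 0,   -30383,    104755,
  2, 0, 0,-2,    15327,     10321,
  0, 0, 1, 2,   -12528,         0,
  0, 0, 1,-2,    10980,     79661,
  4, 0,-1, 0,    10675,    -34782,
  0, 0, 3, 0,    10034,    -23210,
  4, 0,-2, 0,     8548,    -21636,
  2, 1,-1, 0,    -7888,     24208,
  2, 1, 0, 0,    -6766,     30824,
  1, 0,-1, 0,    -5163,     -8379,
  1, 1, 0, 0,     4987,    -16675,
  2,-1, 1, 0,     4036,    -12831,
  2, 0, 2, 0,     3994,    -10445,
  4, 0, 0, 0,     3861,    -11650,
  2, 0,-3, 0,     3665,     14403,
  0, 1,-2, 0,    -2689,     -7003,
  2, 0,-1, 2,    -2602,         0,
  2,-1,-2, 0,     2390,     10056,
  1, 0, 1, 0,    -2348,      6322,
  2,-2, 0, 0,     2236,     -9884,
  0, 1, 2, 0,    -2120,      5751,
  0, 2, 0, 0,    -2069,         0,
  2,-2,-1, 0,     2048,     -4950,
  2, 0, 1,-2,    -1773,      4130,
  2, 0, 0, 2,    -1595,         0,
  4,-1,-1, 0,     1215,     -3958,
  0, 0, 2, 2,    -1110,         0,
  3, 0,-1, 0,     -892,      3258,
  2, 1, 1, 0,     -810,      2616,
  4,-1,-2, 0,      759,     -1897,
  0, 2,-1, 0,     -713,     -2117,
  2, 2,-1, 0,     -700,      2354,
  2, 1,-2, 0,      691,         0,
  2,-1, 0,-2,      596,         0,
  4, 0, 1, 0,      549,     -1423,
  0, 0, 4, 0,      537,     -1117,
  4,-1, 0, 0,      520,     -1571,
  1, 0,-2, 0,     -487,     -1739
), ncol = 6, byrow = TRUE)

# Latitude terms: multiples of (D, M, Mp, F); sb in 1e-6 deg.
MOON_B <- matrix(c(
  0, 0, 0, 1,  5128122,
  0, 0, 1, 1,   280602,
  0, 0, 1,-1,   277693,
  2, 0, 0,-1,   173237,
  2, 0,-1, 1,    55413,
  2, 0,-1,-1,    46271,
  2, 0, 0, 1,    32573,
  0, 0, 2, 1,    17198,
  2, 0, 1,-1,     9266,
  0, 0, 2,-1,     8822,
  2,-1, 0,-1,     8216,
  2, 0,-2,-1,     4324,
  2, 0, 1, 1,     4200,
  2, 1, 0,-1,    -3359,
  2,-1,-1, 1,     2463,
  2,-1, 0, 1,     2211,
  2,-1,-1,-1,     2065,
  0, 1,-1,-1,    -1870,
  4, 0,-1,-1,     1828,
  0, 1, 0, 1,    -1794,
  0, 0, 0, 3,    -1749,
  0, 1,-1, 1,    -1565,
  1, 0, 0, 1,    -1491,
  0, 1, 1, 1,    -1475,
  0, 1, 1,-1,    -1410,
  0, 1, 0,-1,    -1344,
  1, 0, 0,-1,    -1335,
  0, 0, 3, 1,     1107,
  4, 0, 0,-1,     1021,
  4, 0,-1, 1,      833
), ncol = 5, byrow = TRUE)

moon_ecliptic <- function(T) {
  Lp <- 218.3164477 + 481267.88123421 * T - 0.0015786 * T^2 + T^3 / 538841
  D  <- 297.8501921 + 445267.1114034  * T - 0.0018819 * T^2 + T^3 / 545868
  M  <- 357.5291092 + 35999.0502909   * T - 0.0001536 * T^2
  Mp <- 134.9633964 + 477198.8675055  * T + 0.0087414 * T^2 + T^3 / 69699
  F  <- 93.2720950  + 483202.0175233  * T - 0.0036539 * T^2 - T^3 / 3526000
  A1 <- 119.75 + 131.849 * T
  A2 <- 53.09 + 479264.290 * T
  A3 <- 313.45 + 481266.484 * T
  E  <- 1 - 0.002516 * T - 0.0000074 * T^2

  arg_lr <- deg2rad(MOON_LR[, 1] * D + MOON_LR[, 2] * M +
                    MOON_LR[, 3] * Mp + MOON_LR[, 4] * F)
  ef_lr <- E^abs(MOON_LR[, 2])
  sl <- sum(MOON_LR[, 5] * ef_lr * sin(arg_lr)) +
    3958 * sin(deg2rad(A1)) + 1962 * sin(deg2rad(Lp - F)) + 318 * sin(deg2rad(A2))
  sr <- sum(MOON_LR[, 6] * ef_lr * cos(arg_lr))

  arg_b <- deg2rad(MOON_B[, 1] * D + MOON_B[, 2] * M +
                   MOON_B[, 3] * Mp + MOON_B[, 4] * F)
  ef_b <- E^abs(MOON_B[, 2])
  sb <- sum(MOON_B[, 5] * ef_b * sin(arg_b)) -
    2235 * sin(deg2rad(Lp)) + 382 * sin(deg2rad(A3)) +
    175 * sin(deg2rad(A1 - F)) + 175 * sin(deg2rad(A1 + F)) +
    127 * sin(deg2rad(Lp - Mp)) - 115 * sin(deg2rad(Lp + Mp))

  list(lambda = wrap_degrees(Lp + sl / 1e6),
       beta = sb / 1e6,
       distance_km = 385000.56 + sr / 1000)
}

# --- frames ------------------------------------------------------------------

gmst_deg <- function(jd_ut) {
  T <- (jd_ut - 2451545.0) / 36525
  wrap_degrees(280.46061837 + 360.98564736629 * (jd_ut - 2451545.0) +
               0.000387933 * T^2 - T^3 / 38710000)
}

ecliptic_to_equatorial <- function(lambda, beta, eps) {
  lr <- deg2rad(lambda); br <- deg2rad(beta); er <- deg2rad(eps)
  ra <- atan2(sin(lr) * cos(er) - tan(br) * sin(er), cos(lr))
  dec <- asin(sin(br) * cos(er) + cos(br) * sin(er) * sin(lr))
  list(ra = wrap_degrees(rad2deg(ra)), dec = rad2deg(dec))
}

equatorial_to_horizontal <- function(ra, dec, jd_ut, site) {
  H <- deg2rad(wrap_degrees(gmst_deg(jd_ut) + site$longitude - ra))
  phi <- deg2rad(site$latitude); d <- deg2rad(dec)
  alt <- asin(sin(phi) * sin(d) + cos(phi) * cos(d) * cos(H))
  az_s <- atan2(sin(H), cos(H) * sin(phi) - tan(d) * cos(phi))  # from south
  list(azimuth = wrap_degrees(rad2deg(az_s) + 180), altitude = rad2deg(alt))
}

# Geocentric -> topocentric equatorial correction (spherical Earth; the
# neglected flattening contributes < 0.01 deg).
topocentric <- function(ra, dec, distance_km, jd_ut, site) {
  par <- asin(6378.14 / distance_km)                 # horizontal parallax, rad
  phi <- deg2rad(site$latitude)
  H <- deg2rad(wrap_degrees(gmst_deg(jd_ut) + site$longitude - ra))
  d <- deg2rad(dec)
  num <- -cos(phi) * sin(par) * sin(H)
  den <- cos(d) - cos(phi) * sin(par) * cos(H)
  dalpha <- atan2(num, den)
  ra_t <- ra + rad2deg(dalpha)
  dec_t <- rad2deg(atan2((sin(d) - sin(phi) * sin(par)) * cos(dalpha), den))
  list(ra = wrap_degrees(ra_t), dec = dec_t)
}

new_ephemeris_state <- function(body, azimuth, altitude, illuminated_fraction,
                                phase_label, utc, site) {
  structure(list(body = body, azimuth = azimuth, altitude = altitude,
                 illuminated_fraction = illuminated_fraction,
                 phase_label = phase_label, above_horizon = altitude > 0,
                 utc = utc, site = site),
            class = "ephemeris_state")
}

#' @export
print.ephemeris_state <- function(x, ...) {
  cat(sprintf("<ephemeris_state> %s @ %s UTC\n  azimuth=%.2f alt=%.2f %s%s\n",
              x$body, format(x$utc, "%Y-%m-%d %H:%M:%S"),
              x$azimuth, x$altitude,
              if (x$above_horizon) "above horizon" else "below horizon",
              if (is.na(x$illuminated_fraction)) "" else
                sprintf("  illum=%.3f phase=%s", x$illuminated_fraction,
                        x$phase_label)))
  invisible(x)
}

#' Topocentric position of the moon
#'
#' Azimuth (degrees clockwise from true north) and altitude of the moon at a
#' site and UTC instant, plus the illuminated fraction and phase label.
#' Accuracy is about 0.1 degree against a rigorous ephemeris, comfortably
#' inside the 1-degree design target. No refraction is applied, so
#' `above_horizon` is the geometric `altitude > 0`.
#'
#' @param utc a POSIXct (or ISO 8601 string), interpreted as UTC;
#'   must fall in 1950-2050.
#' @param site a [site()].
#' @return an `ephemeris_state`.
#' @export
moon_position <- function(utc, site) {
  utc <- check_window(as_utc(utc))
  jd_ut <- julian_day(utc)
  T <- (jd_ut + DELTA_T_S / 86400 - 2451545.0) / 36525
  m <- moon_ecliptic(T)
  eq <- ecliptic_to_equatorial(m$lambda, m$beta, mean_obliquity(T))
  eqt <- topocentric(eq$ra, eq$dec, m$distance_km, jd_ut, site)
  hor <- equatorial_to_horizontal(eqt$ra, eqt$dec, jd_ut, site)
  new_ephemeris_state("moon", hor$azimuth, hor$altitude,
                      illuminated_fraction(utc), phase_label(utc), utc, site)
}

#' Geocentric position of the sun
#'
#' As [moon_position()] but for the sun (solar parallax < 0.003 degrees is
#' neglected). Accuracy about 0.01 degrees.
#'
#' @inheritParams moon_position
#' @return an `ephemeris_state` (`illuminated_fraction` is `NA` for the sun).
#' @export
sun_position <- function(utc, site) {
  utc <- check_window(as_utc(utc))
  jd_ut <- julian_day(utc)
  T <- (jd_ut + DELTA_T_S / 86400 - 2451545.0) / 36525
  s <- sun_ecliptic(T)
  eq <- ecliptic_to_equatorial(s$lambda, s$beta, mean_obliquity(T))
  hor <- equatorial_to_horizontal(eq$ra, eq$dec, jd_ut, site)
  new_ephemeris_state("sun", hor$azimuth, hor$altitude, NA_real_,
                      NA_character_, utc, site)
}

# Geocentric sun-moon elongation, degrees in [0, 180].
elongation_deg <- function(utc) {
  utc <- check_window(as_utc(utc))
  T <- (julian_day(utc) + DELTA_T_S / 86400 - 2451545.0) / 36525
  m <- moon_ecliptic(T); s <- sun_ecliptic(T)
  cospsi <- cos(deg2rad(m$beta)) * cos(deg2rad(m$lambda - s$lambda))
  rad2deg(acos(pmin(pmax(cospsi, -1), 1)))
}

# Ecliptic-longitude difference moon - sun in [0, 360); < 180 = waxing.
phase_angle_deg <- function(utc) {
  utc <- check_window(as_utc(utc))
  T <- (julian_day(utc) + DELTA_T_S / 86400 - 2451545.0) / 36525
  wrap_degrees(moon_ecliptic(T)$lambda - sun_ecliptic(T)$lambda)
}

#' Illuminated fraction of the lunar disc
#'
#' `k = (1 - cos(psi)) / 2` with `psi` the geocentric sun-moon elongation:
#' 0 at new moon, 1 at full moon.
#'
#' @inheritParams moon_position
#' @return fraction in \[0, 1\].
#' @export
illuminated_fraction <- function(utc) {
  (1 - cos(deg2rad(elongation_deg(utc)))) / 2
}

#' Lunar phase label at an instant
#'
#' Classifies by the moon-sun ecliptic longitude difference `d` (0 = new,
#' 90 = first quarter, 180 = full, 270 = third quarter) with +-22.5-degree
#' windows around the four principal phases; instants outside the windows are
#' labelled `waxing` (`d < 180`) or `waning`.
#'
#' @inheritParams moon_position
#' @return one of `"new"`, `"first_quarter"`, `"full"`, `"third_quarter"`,
#'   `"waxing"`, `"waning"`.
#' @export
phase_label <- function(utc) {
  d <- phase_angle_deg(utc)
  if (d <= 22.5 || d >= 337.5) return("new")
  if (abs(d - 90) <= 22.5) return("first_quarter")
  if (abs(d - 180) <= 22.5) return("full")
  if (abs(d - 270) <= 22.5) return("third_quarter")
  if (d < 180) "waxing" else "waning"
}

#' UTC instant of local solar noon
#'
#' Mean solar noon at a longitude (civil-clock conventions are irrelevant to
#' the analysis; the illuminated fraction moves by < 0.01 over any plausible
#' definition of "noon").
#'
#' @param date a `Date` or "YYYY-MM-DD" string.
#' @param longitude degrees east.
#' @return POSIXct, UTC.
#' @export
local_solar_noon <- function(date, longitude) {
  d <- as.Date(date)
  as.POSIXct(as.numeric(as.POSIXct(paste(d, "12:00:00"), tz = "UTC")) -
               longitude / 15 * 3600,
             origin = "1970-01-01", tz = "UTC")
}

#' Gravitational pull of a celestial body on a mass
#'
#' Worked-example utility: Newtonian attraction `F = G M m / d^2` using the
#' lunar mass 7.342e22 kg at the mean Earth-moon distance 3.844e8 m, the solar
#' mass 1.989e30 kg at 1 au, or, for `body = "earth"`, the surface weight
#' `m g` with `g = 9.81 m s^-2`.
#'
#' @param mass_kg mass being attracted, kg (> 0 allowed to be 0).
#' @param body `"moon"`, `"sun"` or `"earth"`.
#' @return force in newtons.
#' @export
gravitational_pull <- function(mass_kg, body = c("moon", "earth", "sun")) {
  body <- match.arg(body)
  stopifnot(is.finite(mass_kg), mass_kg >= 0)
  G <- 6.674e-11
  switch(body,
         moon  = G * 7.342e22 * mass_kg / 3.844e8^2,
         sun   = G * 1.989e30 * mass_kg / 1.496e11^2,
         earth = mass_kg * 9.81)
}
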