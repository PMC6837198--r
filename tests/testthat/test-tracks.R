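test_that("track and compass files round-trip through the dialect", {
  cal <- default_cal()
  tr <- track_at_angles(runif(900, 0, 360), cal, t_s = 0:899, id = "rt")
  cp <- flat_compass(0:899, 123.456)
  tdir <- withr::local_tempdir()
  tpath <- file.path(tdir, "rt_track.csv")
  cpath <- file.path(tdir, "rt_compass.csv")
  write_track(tr, tpath)
  write_compass(cp, cpath)
  tr2 <- read_track(tpath, id = "rt")
  cp2 <- read_compass(cpath)
  expect_equal(nrow(tr2), 900)
  expect_equal(tr2$t_s, tr$t_s)
  expect_equal(tr2$x_px, tr$x_px, tolerance = 1e-6)
  expect_equal(tr2$y_px, tr$y_px, tolerance = 1e-6)
  expect_equal(attr(tr2, "y_axis"), "up")
  expect_equal(cp2$heading_deg, cp$heading_deg, tolerance = 1e-6)
})

test_that("malformed files are rejected with line numbers", {
  tdir <- withr::local_tempdir()
  p <- file.path(tdir, "bad.csv")
  writeLines(c("t_s,x_px,y_px", "0,1,2", "1,3,4", "1,5,6"), p)
  expect_error(read_track(p), "duplicated timestamp at line 4")
  writeLines(c("t_s,x_px", "0,1"), p)
  expect_error(read_track(p), "missing required columns: y_px")
  writeLines(c("t_s,x_px,y_px", "0,1,2", "1,zz,4"), p)
  expect_error(read_track(p), "non-numeric 'x_px' at lines 3")
  writeLines(c("t_s,heading_deg", "0,10", "oops"), p)
  expect_error(read_compass(p), "malformed rows at lines 3")
})

test_that("deployment metadata round-trips and requires tide phase", {
  tdir <- withr::local_tempdir()
  p <- file.path(tdir, "meta.txt")
  meta <- default_meta()
  write_deployment_meta(meta, default_cal(), p)
  md <- read_deployment_meta(p)
  expect_equal(md$meta$id, meta$id)
  expect_equal(md$meta$tide_phase, "ebb")
  expect_equal(as.numeric(md$meta$utc_start), as.numeric(meta$utc_start))
  expect_equal(md$cal$radius_px, 400)
  expect_error(deployment_meta("x", "2015-01-01", 60, 5, NULL), "tide_phase")
})

test_that("bearing extraction rotates camera angles by the compass heading", {
  cal <- default_cal()
  meta <- default_meta(acclimation_s = 0, analysis_s = 10)
  tr <- track_at_angles(rep(0, 10), cal)          # head image-up of centre
  expect_equal(as.numeric(bearings_from_track(tr, flat_compass(0:9, 0), cal, meta)),
               rep(0, 10))
  expect_equal(as.numeric(bearings_from_track(tr, flat_compass(0:9, 90), cal, meta)),
               rep(90, 10))
})

test_that("compass correction cancels an arbitrary rigid camera rotation", {
  cal <- default_cal()
  meta <- default_meta(acclimation_s = 0, analysis_s = 200)
  set.seed(5)
  true_bearings <- runif(200, 0, 360)
  rot <- runif(200, 0, 360)   # arbitrary chamber rotation per second
  tr <- track_at_angles(true_bearings - rot, cal, t_s = 0:199)
  cp <- structure(data.frame(t_s = 0:199, heading_deg = wrap_degrees(rot)),
                  class = c("compass_series", "data.frame"))
  got <- as.numeric(bearings_from_track(tr, cp, cal, meta))
  expect_lt(max(abs(angular_deviation(got, wrap_degrees(true_bearings)))), 1e-9)
})

test_that("analysis window trims exactly 300 <= t < 900 and flags coverage", {
  cal <- default_cal()
  meta <- default_meta()
  tr <- track_at_angles(rep(45, 900), cal, t_s = 0:899)
  cp <- flat_compass(0:899, 0)
  b <- bearings_from_track(tr, cp, cal, meta)
  expect_equal(length(b), 600)
  expect_equal(range(attr(b, "t_s")), c(300, 899))
  expect_false(attr(b, "low_coverage"))

  # drop 30% of analysis seconds -> low coverage flag
  keep <- c(0:299, seq(300, 899, by = 2), 600:749)
  tr2 <- tr[tr$t_s %in% keep, ]
  attr(tr2, "y_axis") <- "up"; attr(tr2, "id") <- "gap"
  class(tr2) <- c("track", "data.frame")
  b2 <- suppressWarnings(bearings_from_track(tr2, cp, cal, meta))
  expect_true(attr(b2, "low_coverage"))

  # sparse compass: > 10% of samples unmatched within 1 s
  cp5 <- flat_compass(seq(0, 899, by = 5), 0)
  expect_error(bearings_from_track(tr, cp5, cal, meta), "compass coverage")
})

test_that("y-down dialect is normalised about the calibrated centre", {
  cal <- default_cal()
  meta <- default_meta(acclimation_s = 0, analysis_s = 4)
  tr <- track_at_angles(c(0, 90, 180, 270), cal)
  trd <- tr
  trd$y_px <- 2 * cal$center_y - tr$y_px   # mirror about the centre line
  attr(trd, "y_axis") <- "down"
  bu <- bearings_from_track(tr, flat_compass(0:3, 0), cal, meta)
  bd <- bearings_from_track(trd, flat_compass(0:3, 0), cal, meta)
  expect_equal(as.numeric(bu), as.numeric(bd), tolerance = 1e-9)
})

test_that("swimming speed: geometry oracles and invariances", {
  meta <- default_meta(acclimation_s = 0, analysis_s = 11)
  # stationary
  cal <- default_cal()
  tr <- track_at_angles(rep(10, 11), cal)
  expect_equal(swimming_speed(tr, cal, meta)$per_second, rep(0, 10))

  # straight crossing of the 40 cm arena in 10 s -> 4 cm/s
  cal2 <- chamber_calibration(0, 0, 100, 20)
  tr2 <- structure(data.frame(t_s = 0:10, x_px = seq(-100, 100, by = 20),
                              y_px = rep(0, 11)),
                   id = "line", y_axis = "up", class = c("track", "data.frame"))
  sp <- swimming_speed(tr2, cal2, meta)
  expect_equal(sp$per_second, rep(4, 10), tolerance = 1e-9)
  expect_equal(sp$mean, 4, tolerance = 1e-9)

  # circular path, radius 10 cm, 1 deg/s -> 2*10*sin(0.5 deg) per second
  meta3 <- default_meta(acclimation_s = 0, analysis_s = 361)
  cal3 <- chamber_calibration(0, 0, 200, 20)
  tr3 <- track_at_angles(0:360, cal3, radius_frac = 0.5, t_s = 0:360)
  sp3 <- swimming_speed(tr3, cal3, meta3)
  expect_equal(mean(sp3$per_second), 2 * 10 * sin(pi / 360), tolerance = 1e-6)
  expect_equal(mean(sp3$per_second), 2 * pi * 10 / 360, tolerance = 1e-3)

  # rescaling pixels with the calibration leaves cm/s unchanged
  cal4 <- chamber_calibration(0, 0, 200, 20)
  tr4 <- tr2
  tr4$x_px <- tr4$x_px * 2
  expect_equal(swimming_speed(tr4, cal4, meta)$per_second,
               swimming_speed(tr2, cal2, meta)$per_second, tolerance = 1e-12)

  # steps spanning gaps are excluded
  tr5 <- tr2[-5, ]
  attr(tr5, "y_axis") <- "up"
  class(tr5) <- c("track", "data.frame")
  expect_length(swimming_speed(tr5, cal2, meta)$per_second, 8)

  expect_error(chamber_calibration(0, 0, -1, 20), "degenerate calibration")
})
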