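test_that("circular_mean matches vector-summation oracle", {
  s <- circular_mean(angle_series(rep(90, 600)))
  expect_equal(s$mean_bearing, 90)
  expect_equal(s$resultant_length, 1)

  s <- circular_mean(angle_series(c(0, 180)))
  expect_lt(s$resultant_length, 1e-12)
  expect_true(is.na(s$mean_bearing))

  # {10, 350}: mean unit vector is (0, cos 10 deg) -> mean 0, Rbar = cos 10
  s <- circular_mean(angle_series(c(10, 350)))
  expect_equal(s$mean_bearing, 0, tolerance = 1e-9)
  expect_equal(s$resultant_length, cos(10 * pi / 180), tolerance = 1e-12)

  expect_error(angle_series(numeric(0)), "no samples")
  expect_error(angle_series(c(1, NA)), "finite")
})

test_that("rayleigh_test degenerate and small-n behaviour", {
  s <- suppressWarnings(rayleigh_test(angle_series(rep(45, 10))))
  expect_equal(s$rayleigh_z, 10)
  expect_gte(s$p_value, 0)
  expect_lte(s$p_value, 1)
  expect_lt(s$p_value, 1e-3)
  expect_warning(rayleigh_test(angle_series(c(1, 2))), "n < 3")
  # Z = n * Rbar^2 bookkeeping
  set.seed(11)
  s <- rayleigh_test(angle_series(runif(50, 0, 360)))
  expect_equal(s$rayleigh_z, s$n * s$resultant_length^2, tolerance = 1e-12)
})

test_that("rotation equivariance, reflection, and p monotonicity", {
  set.seed(42)
  for (rep in 1:5) {
    th <- runif(40, 0, 360)
    shift <- runif(1, 0, 360)
    a <- rayleigh_test(angle_series(th))
    b <- rayleigh_test(angle_series(th + shift))
    expect_equal(wrap_degrees(a$mean_bearing + shift), b$mean_bearing,
                 tolerance = 1e-8)
    expect_equal(a$resultant_length, b$resultant_length, tolerance = 1e-12)
    expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
    r <- rayleigh_test(angle_series(-th))
    expect_equal(r$mean_bearing, wrap_degrees(-a$mean_bearing), tolerance = 1e-8)
    expect_equal(r$resultant_length, a$resultant_length, tolerance = 1e-12)
  }
  for (n in c(5, 20, 80, 600)) {
    p <- vapply(seq(0, 0.8, by = 0.02), function(r) rayleigh_p(n, r), 0)
    expect_true(all(diff(p) <= 0))
    # strictly decreasing until the clamp at 0 kicks in (large n, large Rbar)
    expect_true(all(diff(p[p > 0]) < 0))
  }
})

test_that("second-order test: degenerate groups and consistency", {
  s <- rayleigh_second_order(angle_series(c(0, 180)))
  expect_lt(s$resultant_length, 1e-12)
  expect_equal(s$p_value, 1, tolerance = 1e-6)
  expect_error(rayleigh_second_order(angle_series(10)), "group too small")
  # a group equal to one individual repeated behaves as rayleigh_test of it
  th <- c(10, 30, 50, 350, 20)
  expect_equal(rayleigh_second_order(angle_series(th))$p_value,
               rayleigh_test(angle_series(th))$p_value)
})

test_that("second-order recovery at group sizes and dispersion like the field data", {
  # 45 means ~ vonMises(195, kappa with E[Rbar] = 0.42): the 95% arc should
  # cover 195 in at least 93% of replicates. 2000 replicates rather than a few
  # hundred so the Monte-Carlo s.e. (~0.5%) is small against the 2% margin.
  set.seed(2025)
  kap <- kappa_from_r(0.42)
  hits <- logical(2000)
  defined <- logical(2000)
  for (i in 1:2000) {
    m <- angle_series(rvonmises(45, 195, kap))
    ci <- mean_ci95(m)
    defined[i] <- !any(is.na(ci))
    hits[i] <- isTRUE(ci_contains(ci, 195))
  }
  expect_gte(mean(defined), 0.95)   # the group test almost always rejects
  expect_gte(sum(hits) / sum(defined), 0.93)
})

test_that("confidence arcs: degenerate, coverage, and method cross-check", {
  ci <- mean_ci95(angle_series(rep(123, 30)))
  expect_equal(unname(ci), c(123, 123), tolerance = 1e-6)

  set.seed(7)
  hits <- vapply(1:1000, function(i) {
    ci <- mean_ci95(angle_series(rvonmises(600, 180, 1)))
    isTRUE(ci_contains(ci, 180))
  }, logical(1))
  expect_gte(mean(hits), 0.92)
  expect_lte(mean(hits), 0.98)

  # dispersion arc and bootstrap arc agree within 5 deg of half-width
  set.seed(8)
  th <- angle_series(rvonmises(200, 90, 2))
  ci_a <- mean_ci95(th, method = "dispersion")
  ci_b <- mean_ci95(th, method = "bootstrap")
  half <- function(ci) wrap_degrees(ci[2] - ci[1]) / 2
  expect_lt(abs(half(ci_a) - half(ci_b)), 5)

  # undefined when the test does not reject or n < 5
  set.seed(9)
  expect_true(all(is.na(mean_ci95(angle_series(runif(100, 0, 360))))))
  expect_true(all(is.na(suppressWarnings(mean_ci95(angle_series(c(10, 12, 14)))))))
})

test_that("angular_difference wraps and orients toward the cue", {
  expect_equal(angular_difference(10, 10), 0)
  expect_equal(angular_difference(350, 10), 340)
  expect_equal(angular_difference(195, 179), 16)
  expect_error(angular_difference(NA, 1), "non-finite")
})

test_that("kappa_from_r inverts the von Mises mean resultant", {
  expect_equal(kappa_from_r(0), 0)
  # Bessel-function oracle: A1(0.62919) = I1/I0 = 0.30 (evaluated directly)
  k <- kappa_from_r(0.30)
  expect_equal(besselI(k, 1) / besselI(k, 0), 0.30, tolerance = 1e-6)
  expect_equal(k, 0.63, tolerance = 0.01)
  for (x in seq(0.1, 0.9, by = 0.1)) {
    expect_equal(vm_mean_resultant(kappa_from_r(x)), x, tolerance = 1e-6)
  }
  # monotone
  ks <- vapply(seq(0.05, 0.95, 0.05), kappa_from_r, 0)
  expect_true(all(diff(ks) > 0))
  expect_error(kappa_from_r(1), "degenerate concentration")
})

test_that("rvonmises concentration matches its target", {
  set.seed(123)
  kap <- kappa_from_r(0.30)
  rbars <- vapply(1:500, function(i) {
    rayleigh_test(angle_series(rvonmises(600, 100, kap)))$resultant_length
  }, 0)
  expect_lt(abs(mean(rbars) - 0.30), 0.02)
  # kappa = 0 is uniform: Rbar small at large n
  set.seed(124)
  expect_lt(circular_mean(angle_series(rvonmises(5000, 0, 0)))$resultant_length,
            0.05)
})
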