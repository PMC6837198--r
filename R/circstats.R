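# Circular statistics for orientation data: first-order summaries of one
# animal's per-second bearings, and second-order (one mean bearing per animal)
# group tests. All angles in degrees, clockwise from north.

# Below this mean resultant length the mean direction is numerically undefined.
EPS_R <- 1e-12

circ_moments <- function(theta_deg) {
  th <- deg2rad(theta_deg)
  C <- mean(cos(th))
  S <- mean(sin(th))
  rbar <- sqrt(C^2 + S^2)
  mu <- if (rbar < EPS_R) NA_real_ else wrap_degrees(rad2deg(atan2(S, C)))
  list(mu = mu, rbar = min(rbar, 1))
}

new_circular_summary <- function(mu, rbar, z, p, n, frame,
                                 ci_lower = NA_real_, ci_upper = NA_real_) {
  structure(list(mean_bearing = mu, resultant_length = rbar,
                 rayleigh_z = z, p_value = p, n = n,
                 ci95_lower = ci_lower, ci95_upper = ci_upper,
                 frame = frame),
            class = "circular_summary")
}

#' @export
print.circular_summary <- function(x, ...) {
  cat(sprintf(
    "<circular_summary> n=%d frame=%s\n  mean bearing: %s  Rbar=%.4f  Z=%s  p=%s\n",
    x$n, x$frame,
    if (is.na(x$mean_bearing)) "undefined" else sprintf("%.1f deg", x$mean_bearing),
    x$resultant_length,
    if (is.na(x$rayleigh_z)) "-" else sprintf("%.3f", x$rayleigh_z),
    if (is.na(x$p_value)) "-" else format(x$p_value, digits = 3)))
  if (!is.na(x$ci95_lower)) {
    cat(sprintf("  95%% CI arc: [%.1f, %.1f] deg\n", x$ci95_lower, x$ci95_upper))
  }
  invisible(x)
}

#' Circular mean direction and mean resultant length
#'
#' Mean direction is the argument of the mean unit vector
#' (atan2 of mean sine and cosine), wrapped into \[0, 360); the mean resultant
#' length `Rbar` is that vector's magnitude. When `Rbar` falls below 1e-12
#' (e.g. two antipodal bearings) the mean is undefined and reported as `NA`.
#'
#' @param series an [angle_series] (or numeric vector of degrees).
#' @return a `circular_summary` with `mean_bearing` and `resultant_length`
#'   filled in; test fields are `NA`.
#' @export
circular_mean <- function(series) {
  series <- as_angle_series(series)
  m <- circ_moments(as.numeric(series))
  new_circular_summary(m$mu, m$rbar, NA_real_, NA_real_,
                       length(series), series_frame(series))
}

#' Rayleigh test p-value from sample size and mean resultant length
#'
#' Uses `Z = n * Rbar^2` and the first-order finite-sample correction
#' `p = exp(-Z) * (1 + (2Z - Z^2) / (4n))`, clamped into \[0, 1\]. The
#' correction order is a deliberate choice: at the sample sizes this package
#' targets (individual n of several hundred, groups of 9--80) it agrees with
#' published summary tables at their printed precision, while longer series
#' differ only beyond it (see the methods vignette).
#'
#' @param n sample size.
#' @param rbar mean resultant length in \[0, 1\].
#' @return p-value in \[0, 1\].
#' @export
rayleigh_p <- function(n, rbar) {
  stopifnot(n >= 1, rbar >= 0, rbar <= 1)
  z <- n * rbar^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n))
  min(max(p, 0), 1)
}

#' Rayleigh test of circular uniformity
#'
#' Tests the null of a uniform circular distribution against unimodal
#' clustering, via the statistic `Z = n * Rbar^2` and the corrected p-value of
#' [rayleigh_p()]. Duplicate bearings are legitimate 1 Hz samples and are kept
#' as-is.
#'
#' @param series an [angle_series] (or numeric vector of degrees).
#' @return a full `circular_summary` (mean, `Rbar`, `Z`, `p`).
#' @export
rayleigh_test <- function(series) {
  series <- as_angle_series(series)
  n <- length(series)
  if (n < 3) warning("rayleigh_test: n < 3, p-value is not meaningful")
  m <- circ_moments(as.numeric(series))
  z <- n * m$rbar^2
  new_circular_summary(m$mu, m$rbar, z, rayleigh_p(n, m$rbar),
                       n, series_frame(series))
}

#' Second-order (group-level) Rayleigh test
#'
#' Applies the Rayleigh test to a set of mean bearings, one per individual
#' (equal weighting), to ask whether the animals share a common direction.
#' The caller is responsible for restricting the input to individuals whose
#' own orientation was significant; [analyze_group()] enforces this.
#'
#' @param means an [angle_series] of per-individual mean bearings.
#' @return a `circular_summary` in the frame of `means`.
#' @export
rayleigh_second_order <- function(means) {
  means <- as_angle_series(means)
  if (length(means) < 2) stop("group too small")
  # n = 2 groups are legitimate here (reported, typically non-significant);
  # the small-n caveat of rayleigh_test() need not resurface per group.
  suppressWarnings(rayleigh_test(means))
}

#' 95% confidence arc for a mean direction
#'
#' Large-sample arc from the circular dispersion
#' `delta = (1 - rho2) / (2 Rbar^2)` (with `rho2` the mean cosine of twice the
#' deviations from the mean): half-width `asin(qnorm(0.975) * sqrt(delta/n))`.
#' For small or diffuse samples (`n < 25` or `Rbar < 0.2`) this normal
#' approximation is unreliable and a 2000-replicate bootstrap percentile arc is
#' used instead (set the RNG seed beforehand for reproducibility). The arc is
#' only defined when the Rayleigh test rejects at 0.05 and `n >= 5`; otherwise
#' both bounds are `NA`.
#'
#' @param series an [angle_series].
#' @param boot_reps bootstrap replicates for the fallback arc.
#' @param method `"auto"` (dispersion arc for n >= 25 and Rbar >= 0.2, else
#'   bootstrap), or force `"dispersion"` / `"bootstrap"`.
#' @return named numeric `c(lower, upper)` in degrees (a clockwise arc from
#'   `lower` to `upper` containing the mean), or `c(NA, NA)`.
#' @export
mean_ci95 <- function(series, boot_reps = 2000,
                      method = c("auto", "dispersion", "bootstrap")) {
  method <- match.arg(method)
  series <- as_angle_series(series)
  n <- length(series)
  rt <- suppressWarnings(rayleigh_test(series))
  if (is.na(rt$p_value) || rt$p_value >= 0.05 || n < 5 || is.na(rt$mean_bearing)) {
    return(c(lower = NA_real_, upper = NA_real_))
  }
  mu <- rt$mean_bearing
  rbar <- rt$resultant_length
  use_dispersion <- switch(method,
                           auto = n >= 25 && rbar >= 0.2,
                           dispersion = TRUE,
                           bootstrap = FALSE)
  if (use_dispersion) {
    dev <- deg2rad(as.numeric(series) - mu)
    rho2 <- mean(cos(2 * dev))
    delta <- (1 - rho2) / (2 * rbar^2)
    se <- sqrt(delta / n)
    half <- rad2deg(asin(min(1, stats::qnorm(0.975) * se)))
  } else {
    th <- as.numeric(series)
    devs <- vapply(seq_len(boot_reps), function(i) {
      m <- circ_moments(th[sample.int(n, n, replace = TRUE)])
      if (is.na(m$mu)) NA_real_ else angular_deviation(m$mu, mu)
    }, numeric(1))
    devs <- devs[is.finite(devs)]
    q <- stats::quantile(devs, c(0.025, 0.975), names = FALSE, type = 7)
    half <- max(abs(q))  # symmetric percentile arc around the sample mean
  }
  half <- min(half, 179.999)
  c(lower = wrap_degrees(mu - half), upper = wrap_degrees(mu + half))
}

#' Does a confidence arc contain a direction?
#'
#' @param ci `c(lower, upper)` from [mean_ci95()].
#' @param bearing direction in degrees.
#' @return logical.
#' @export
ci_contains <- function(ci, bearing) {
  if (any(is.na(ci))) return(NA)
  width <- wrap_degrees(ci[[2]] - ci[[1]])
  pos <- wrap_degrees(bearing - ci[[1]])
  pos <= width
}

#' Mean resultant length of a von Mises distribution
#'
#' `A1(kappa) = I1(kappa) / I0(kappa)`, computed with exponentially scaled
#' Bessel functions for stability at large `kappa`.
#'
#' @param kappa concentration parameter, `kappa >= 0`.
#' @return expected mean resultant length in \[0, 1).
#' @export
vm_mean_resultant <- function(kappa) {
  ifelse(kappa == 0, 0,
         besselI(kappa, 1, expon.scaled = TRUE) /
           besselI(kappa, 0, expon.scaled = TRUE))
}

#' Invert the von Mises concentration from a mean resultant length
#'
#' Solves `A1(kappa) = rbar` numerically to |A1(kappa) - rbar| < 1e-6;
#' monotone in `rbar`.
#'
#' @param rbar target mean resultant length, `0 <= rbar < 1`.
#' @return concentration `kappa >= 0`.
#' @export
kappa_from_r <- function(rbar) {
  stopifnot(length(rbar) == 1, is.finite(rbar), rbar >= 0)
  if (rbar >= 1) stop("degenerate concentration")
  if (rbar == 0) return(0)
  f <- function(k) vm_mean_resultant(k) - rbar
  upper <- 2
  while (f(upper) < 0) upper <- upper * 2
  stats::uniroot(f, c(1e-12, upper), tol = 1e-10)$root
}

#' Sample from a von Mises distribution
#'
#' Best--Fisher (1979) wrapped-Cauchy envelope rejection sampler, vectorised;
#' `kappa = 0` falls back to the uniform distribution.
#'
#' @param n number of draws.
#' @param mu_deg mean direction, degrees.
#' @param kappa concentration, `kappa >= 0`.
#' @return degrees in \[0, 360).
#' @export
rvonmises <- function(n, mu_deg, kappa) {
  stopifnot(n >= 0, kappa >= 0)
  if (n == 0) return(numeric(0))
  if (kappa == 0) return(wrap_degrees(stats::runif(n, 0, 360)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- ceiling((n - length(out)) * 1.6) + 8
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    th <- sign(u3[ok] - 0.5) * acos(pmin(pmax(f[ok], -1), 1))
    out <- c(out, th)
  }
  wrap_degrees(mu_deg + rad2deg(out[seq_len(n)]))
}
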