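# Ground-truthed synthetic deployments: a hierarchical von Mises world with a
# rotating chamber, built so that bearings_from_track() recovers the simulated
# magnetic bearing series exactly (the compass series records the chamber
# heading used to rotate them). Defaults emulate the field protocol this
# package targets: 15-min deployments at 1 Hz (300 s acclimation + 600 s
# analysis), individual mean resultant lengths near 0.30, ~3 cm/s swimming
# speeds, and campaign sizes per moon phase like the study design.

#' Parameters of the synthetic world
#'
#' @param mu_pop population preferred direction, degrees (ignored per
#'   deployment when `moon_following = TRUE`).
#' @param kappa_pop between-individual von Mises concentration of preferred
#'   directions; default `kappa_from_r(0.42)`, matching group-level resultant
#'   lengths near 0.42.
#' @param kappa_within within-track concentration of per-second bearings;
#'   default `kappa_from_r(0.30)` so individual mean resultant lengths land
#'   near 0.30 at n = 600.
#' @param p_orient probability that an individual orients at all; default
#'   0.96 (the high end of observed orienting proportions). Non-orienting
#'   individuals swim with uniformly distributed bearings.
#' @param sigma_rot s.d. of the wrapped-normal chamber-rotation increments,
#'   degrees per second; default 2.
#' @param speed_median median per-second swimming speed, cm s^-1; default 3.0.
#' @param speed_logsd log-scale s.d. of the lognormal speed distribution;
#'   default 0.22 (gives mean +- s.d. close to 3.0 +- 0.7 cm s^-1).
#' @param seed global integer seed; per-deployment substreams are derived from
#'   it by a counter, so campaigns are reproducible deployment-by-deployment.
#' @param moon_following if `TRUE`, each deployment's population direction is
#'   the deployment's (magnetic) moon azimuth plus `mu_offset`.
#' @param mu_offset degrees added to the moon azimuth when `moon_following`.
#' @return a `synthetic_truth` list.
#' @export
synthetic_truth <- function(mu_pop = 195,
                            kappa_pop = kappa_from_r(0.42),
                            kappa_within = kappa_from_r(0.30),
                            p_orient = 0.96,
                            sigma_rot = 2,
                            speed_median = 3.0,
                            speed_logsd = 0.22,
                            seed = 1L,
                            moon_following = FALSE,
                            mu_offset = 0) {
  stopifnot(kappa_pop >= 0, kappa_within >= 0,
            p_orient >= 0, p_orient <= 1, sigma_rot >= 0,
            speed_median > 0, speed_logsd >= 0)
  structure(list(mu_pop = wrap_degrees(mu_pop), kappa_pop = kappa_pop,
                 kappa_within = kappa_within, p_orient = p_orient,
                 sigma_rot = sigma_rot, speed_median = speed_median,
                 speed_logsd = speed_logsd, seed = as.integer(seed),
                 moon_following = isTRUE(moon_following),
                 mu_offset = mu_offset),
            class = "synthetic_truth")
}

# Deterministic per-deployment substream seed, kept below 2^31.
substream_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483647)
}

#' Simulate one chamber deployment
#'
#' Draws an individual preferred direction `mu_i ~ vonMises(mu_pop, kappa_pop)`
#' with probability `p_orient` (otherwise the individual is a non-orienter:
#' uniform bearings), per-second magnetic bearings
#' `theta_t ~ vonMises(mu_i, kappa_within)`, a wrapped-normal random-walk
#' chamber heading `phi_t`, and camera-frame head angles
#' `wrap(theta_t - phi_t)`. Head positions are placed on those camera angles
#' at radii chosen so that consecutive step lengths match lognormal per-second
#' speeds whenever geometrically feasible (radii restricted to 5-95% of the
#' arena radius; infeasible steps take the nearest feasible radius; because
#' consecutive bearings are drawn independently, wide direction changes at
#' finite radius put a geometric floor under some steps, inflating realised
#' speeds by roughly 20% over the lognormal target -- location contrasts are
#' preserved). Steps
#' longer than the arena diameter are clipped with a warning.
#'
#' @param truth a [synthetic_truth].
#' @param meta a [deployment_meta] (defines row count:
#'   `acclimation_s + analysis_s` seconds at 1 Hz).
#' @param cal a [chamber_calibration].
#' @param moon_azimuth_magnetic deployment moon azimuth in the magnetic frame,
#'   degrees; required when `truth$moon_following`.
#' @param index deployment counter used to derive the RNG substream.
#' @return a list with `track`, `compass` and `truth_record` (the hidden
#'   per-deployment ground truth: orienter flag, `mu_i`, target direction,
#'   substream seed).
#' @export
simulate_deployment <- function(truth, meta, cal,
                                moon_azimuth_magnetic = NULL, index = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(substream_seed(truth$seed, index))
  mu_target <- if (truth$moon_following) {
    if (is.null(moon_azimuth_magnetic)) {
      stop("moon_following truth needs moon_azimuth_magnetic")
    }
    wrap_degrees(moon_azimuth_magnetic + truth$mu_offset)
  } else truth$mu_pop

  orienter <- stats::runif(1) < truth$p_orient
  if (orienter) {
    mu_i <- if (is.infinite(truth$kappa_pop)) mu_target else
      rvonmises(1, mu_target, truth$kappa_pop)
    kw <- truth$kappa_within
  } else {
    mu_i <- wrap_degrees(stats::runif(1, 0, 360))
    kw <- 0
  }

  n <- as.integer(meta$acclimation_s + meta$analysis_s)
  t_s <- seq_len(n) - 1L
  theta <- if (is.infinite(kw)) rep(mu_i, n) else rvonmises(n, mu_i, kw)
  phi <- wrap_degrees(stats::runif(1, 0, 360) +
                        cumsum(c(0, stats::rnorm(n - 1, 0, truth$sigma_rot))))
  theta_cam <- wrap_degrees(theta - phi)

  px_per_cm <- cal$radius_px / cal$radius_cm
  step_px <- stats::rlnorm(n - 1, log(truth$speed_median), truth$speed_logsd) *
    px_per_cm
  max_step <- 2 * 0.95 * cal$radius_px
  if (any(step_px > max_step)) {
    warning("impossible geometry: step length exceeds arena diameter; clipped")
    step_px <- pmin(step_px, max_step)
  }

  rmin <- 0.05 * cal$radius_px
  rmax <- 0.95 * cal$radius_px
  ux <- sin(deg2rad(theta_cam)); uy <- cos(deg2rad(theta_cam))
  x <- numeric(n); y <- numeric(n)
  r0 <- stats::runif(1, 0.3, 0.9) * cal$radius_px
  x[1] <- r0 * ux[1]; y[1] <- r0 * uy[1]
  rprev <- r0
  for (i in 2:n) {
    b <- ux[i] * x[i - 1] + uy[i] * y[i - 1]
    disc <- b^2 - (x[i - 1]^2 + y[i - 1]^2 - step_px[i - 1]^2)
    if (disc >= 0) {
      sq <- sqrt(disc)
      cand <- c(b + sq, b - sq)
      cand <- cand[cand >= rmin & cand <= rmax]
      r <- if (length(cand)) cand[which.min(abs(cand - rprev))] else
        min(max(b, rmin), rmax)
    } else {
      r <- min(max(b, rmin), rmax)
    }
    x[i] <- r * ux[i]; y[i] <- r * uy[i]
    rprev <- r
  }

  track <- structure(
    data.frame(t_s = t_s, x_px = cal$center_x + x, y_px = cal$center_y + y),
    id = meta$id, y_axis = "up", class = c("track", "data.frame"))
  compass <- structure(data.frame(t_s = t_s, heading_deg = phi),
                       class = c("compass_series", "data.frame"))
  list(track = track, compass = compass,
       truth_record = list(id = meta$id, seed = substream_seed(truth$seed, index),
                           orienter = orienter, mu_i = mu_i,
                           mu_target = mu_target, kappa_within = kw))
}

#' Deployment calendar mirroring the study design
#'
#' 203 daytime deployments across the four principal moon phases (57 full
#' moon, 11-16 Apr 2017; 32 third quarter, 19-20 Apr 2017; 53 + 30 new moon,
#' 17-21 Apr 2015 and 27 Apr 2017; 31 first quarter, 3-4 May 2017) at two
#' western-Norway fjord sites, with ebb/flood tide labels alternating in
#' half-day blocks (tide phase is metadata, never computed).
#'
#' @return a data.frame with columns `id, utc_start, lat, lon, tide_phase,
#'   site_name`.
#' @export
default_campaign_calendar <- function() {
  spread <- function(prefix, dates, n, hours = c(7, 9, 11, 13, 15)) {
    slots <- expand.grid(hour = hours, date = dates, stringsAsFactors = FALSE)
    slots <- slots[rep(seq_len(nrow(slots)), length.out = n), ]
    data.frame(id = sprintf("%s_%03d", prefix, seq_len(n)),
               utc_start = sprintf("%sT%02d:%s:00", slots$date, slots$hour,
                                   sprintf("%02d", (seq_len(n) * 7) %% 60)),
               tide_phase = ifelse(slots$hour <= 11, "flood", "ebb"),
               stringsAsFactors = FALSE)
  }
  blocks <- rbind(
    spread("full",  sprintf("2017-04-%02d", 11:16), 57),
    spread("thirdq", sprintf("2017-04-%02d", 19:20), 32),
    spread("new15", sprintf("2015-04-%02d", 17:21), 53),
    spread("new17", "2017-04-27", 30),
    spread("firstq", sprintf("2017-05-%02d", 3:4), 31))
  sites <- rep(c("Langenuen", "Stolmen"), length.out = nrow(blocks))
  blocks$lat <- ifelse(sites == "Langenuen", 60.09, 60.00)
  blocks$lon <- ifelse(sites == "Langenuen", 5.28, 5.04)
  blocks$site_name <- sites
  blocks[, c("id", "utc_start", "lat", "lon", "tide_phase", "site_name")]
}

#' Simulate a whole deployment campaign
#'
#' Runs [simulate_deployment()] over a calendar of instants and sites, labels
#' each deployment with the computed moon conditions at its midpoint, and
#' optionally writes the full file tree (track, compass and metadata files in
#' the dialects of [read_track()] plus `manifest.csv` and a hidden-parameter
#' `truth.tsv` ledger). Byte-identical output for equal seeds.
#'
#' @param calendar a data.frame like [default_campaign_calendar()].
#' @param truth a [synthetic_truth], or a named list of them keyed by moon
#'   phase label (with optional element `"default"`).
#' @param cal a [chamber_calibration] shared by all deployments.
#' @param declination magnetic declination (degrees east) used to express moon
#'   azimuths in the magnetic frame.
#' @param out_dir if non-`NULL`, directory to write the campaign files into.
#' @return (invisibly) a list with `deployments` (each as returned by
#'   [simulate_deployment()] plus `meta`), `truth_table` (data.frame ledger)
#'   and `manifest` (data.frame; `NULL` paths unless written).
#' @export
simulate_campaign <- function(calendar, truth,
                              cal = chamber_calibration(512, 512, 400, 20),
                              declination = 0, out_dir = NULL) {
  stopifnot(is.data.frame(calendar), nrow(calendar) >= 1)
  pick_truth <- function(phase) {
    if (inherits(truth, "synthetic_truth")) return(truth)
    truth[[phase]] %||% truth[["default"]] %||%
      stop("no synthetic_truth for phase ", phase)
  }
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  deployments <- vector("list", nrow(calendar))
  ledger <- vector("list", nrow(calendar))
  manifest <- data.frame(id = character(0), track = character(0),
                         compass = character(0), meta = character(0),
                         stringsAsFactors = FALSE)
  for (i in seq_len(nrow(calendar))) {
    row <- calendar[i, ]
    meta <- deployment_meta(row$id, row$utc_start, row$lat, row$lon,
                            row$tide_phase, row$site_name)
    st <- site(row$lat, row$lon, declination)
    mid <- meta$utc_start + (meta$acclimation_s + meta$analysis_s) / 2
    moon <- moon_position(mid, st)
    az_mag <- wrap_degrees(moon$azimuth - declination)
    tr_i <- pick_truth(moon$phase_label)
    dep <- simulate_deployment(tr_i, meta, cal,
                               moon_azimuth_magnetic = az_mag, index = i)
    dep$meta <- meta
    deployments[[i]] <- dep
    ledger[[i]] <- data.frame(
      id = meta$id, seed = dep$truth_record$seed,
      orienter = dep$truth_record$orienter,
      mu_i = dep$truth_record$mu_i, mu_target = dep$truth_record$mu_target,
      kappa_within = dep$truth_record$kappa_within,
      moon_phase = moon$phase_label, moon_azimuth_magnetic = az_mag,
      moon_altitude = moon$altitude, tide_phase = meta$tide_phase,
      stringsAsFactors = FALSE)
    if (!is.null(out_dir)) {
      paths <- file.path(out_dir, sprintf("%s_%s", meta$id,
                                          c("track.csv", "compass.csv", "meta.txt")))
      write_track(dep$track, paths[1])
      write_compass(dep$compass, paths[2])
      write_deployment_meta(meta, cal, paths[3])
      manifest <- rbind(manifest, data.frame(
        id = meta$id, track = basename(paths[1]), compass = basename(paths[2]),
        meta = basename(paths[3]), stringsAsFactors = FALSE))
    }
  }
  truth_table <- do.call(rbind, ledger)
  if (!is.null(out_dir)) {
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.table(truth_table, file.path(out_dir, "truth.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    manifest <- NULL
  }
  invisible(list(deployments = deployments, truth_table = truth_table,
                 manifest = manifest, cal = cal))
}
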