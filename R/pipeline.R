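# Orchestration: per-individual inference, the p < 0.05 significance filter,
# condition classification from the ephemeris, moon-relative transformation,
# second-order group tests, speed contrasts, and a stratified summary table.

PHASE_ORDER <- c("full", "third_quarter", "new", "first_quarter",
                 "waxing", "waning")

#' Classify deployment conditions at the chamber midpoint
#'
#' The ephemeris reference instant is the deployment midpoint
#' (`utc_start + (acclimation_s + analysis_s)/2`, i.e. start + 7.5 min with
#' defaults); lunar azimuth moves by under 2 degrees across a 15-min
#' deployment, so the choice of instant is immaterial. `moon_above_horizon`
#' uses the strict geometric test `altitude > 0` (an altitude of exactly 0
#' classifies as below). Tide phase is copied from the metadata, never
#' computed. Azimuths are also returned in the magnetic frame
#' (`azimuth - declination`), the frame of the compass-corrected bearings.
#'
#' @param meta a [deployment_meta].
#' @param st a [site()] (carries the declination).
#' @return a list: `moon_phase`, `moon_above_horizon`, `moon_azimuth`
#'   (true), `moon_azimuth_magnetic`, `moon_altitude`, `sun_azimuth`,
#'   `sun_azimuth_magnetic`, `sun_above_horizon`, `tide_phase`, `midpoint`.
#' @export
classify_conditions <- function(meta, st) {
  mid <- meta$utc_start + (meta$acclimation_s + meta$analysis_s) / 2
  moon <- moon_position(mid, st)
  sun <- sun_position(mid, st)
  list(moon_phase = moon$phase_label,
       moon_above_horizon = moon$altitude > 0,
       moon_azimuth = moon$azimuth,
       moon_azimuth_magnetic = wrap_degrees(moon$azimuth - st$magnetic_declination),
       moon_altitude = moon$altitude,
       moon_illuminated_fraction = moon$illuminated_fraction,
       sun_azimuth = sun$azimuth,
       sun_azimuth_magnetic = wrap_degrees(sun$azimuth - st$magnetic_declination),
       sun_above_horizon = sun$altitude > 0,
       tide_phase = meta$tide_phase,
       midpoint = mid)
}

#' Analyse one individual deployment
#'
#' Bearings are extracted with [bearings_from_track()], tested with
#' [rayleigh_test()], and the mean bearing re-expressed relative to the
#' deployment's magnetic moon azimuth (one alpha_moon value per individual)
#' and sun azimuth. Deployments flagged low-coverage (< 80% of analysis
#' seconds retained) are returned with `excluded = TRUE` and a reason, and are
#' dropped by [analyze_group()].
#'
#' @param track,compass,cal,meta as in [bearings_from_track()].
#' @param st a [site()]; defaults to the deployment coordinates with zero
#'   declination.
#' @param alpha individual significance level (default 0.05).
#' @return an `individual_result` list.
#' @export
analyze_individual <- function(track, compass, cal, meta,
                               st = site(meta$latitude, meta$longitude),
                               alpha = 0.05) {
  cond <- classify_conditions(meta, st)
  bearings <- bearings_from_track(track, compass, cal, meta)
  mag <- rayleigh_test(bearings)
  speed <- swimming_speed(track, cal, meta)
  excluded <- isTRUE(attr(bearings, "low_coverage"))
  alpha_moon <- if (!is.na(mag$mean_bearing)) {
    angular_difference(mag$mean_bearing, cond$moon_azimuth_magnetic)
  } else NA_real_
  alpha_sun <- if (!is.na(mag$mean_bearing)) {
    angular_difference(mag$mean_bearing, cond$sun_azimuth_magnetic)
  } else NA_real_
  structure(list(id = meta$id, magnetic = mag,
                 moon_relative_bearing = alpha_moon,
                 sun_relative_bearing = alpha_sun,
                 significant = !is.na(mag$p_value) && mag$p_value < alpha,
                 mean_speed = speed$mean, median_speed = speed$median,
                 conditions = cond,
                 coverage = attr(bearings, "coverage"),
                 excluded = excluded,
                 exclusion_reason = if (excluded) "low coverage" else NA_character_),
            class = "individual_result")
}

individuals_to_df <- function(results) {
  do.call(rbind, lapply(results, function(r) data.frame(
    id = r$id,
    mean_bearing = r$magnetic$mean_bearing,
    resultant_length = r$magnetic$resultant_length,
    p_value = r$magnetic$p_value,
    n = r$magnetic$n,
    alpha_moon = r$moon_relative_bearing,
    alpha_sun = r$sun_relative_bearing,
    significant = r$significant,
    mean_speed = r$mean_speed,
    median_speed = r$median_speed,
    moon_phase = r$conditions$moon_phase,
    tide_phase = r$conditions$tide_phase,
    moon_above_horizon = r$conditions$moon_above_horizon,
    coverage = r$coverage,
    excluded = r$excluded,
    stringsAsFactors = FALSE)))
}

group_row <- function(df, keys, sun_frame = FALSE) {
  sig <- df[df$significant, , drop = FALSE]
  n_tested <- nrow(df)
  N <- nrow(sig)
  summarize_frame <- function(values, frame) {
    if (N >= 2) {
      rayleigh_second_order(angle_series(values, frame))
    } else NULL
  }
  mag <- summarize_frame(sig$mean_bearing, "magnetic_north")
  moo <- summarize_frame(sig$alpha_moon, "moon_relative")
  out <- data.frame(
    keys,
    n_tested = n_tested, N = N,
    prop_significant = N / n_tested,
    mean_R = mean(df$resultant_length), sd_R = stats::sd(df$resultant_length),
    mag_mean_bearing = if (!is.null(mag)) mag$mean_bearing else NA_real_,
    mag_r = if (!is.null(mag)) mag$resultant_length else NA_real_,
    mag_p = if (!is.null(mag)) mag$p_value else NA_real_,
    moon_mean_bearing = if (!is.null(moo)) moo$mean_bearing else NA_real_,
    moon_r = if (!is.null(moo)) moo$resultant_length else NA_real_,
    moon_p = if (!is.null(moo)) moo$p_value else NA_real_,
    insufficient = N < 2,
    stringsAsFactors = FALSE)
  if (sun_frame) {
    su <- summarize_frame(sig$alpha_sun, "sun_relative")
    out$sun_mean_bearing <- if (!is.null(su)) su$mean_bearing else NA_real_
    out$sun_r <- if (!is.null(su)) su$resultant_length else NA_real_
    out$sun_p <- if (!is.null(su)) su$p_value else NA_real_
  }
  out
}

#' Group-level (second-order) analysis
#'
#' Stratifies individual results by condition keys (default: moon phase, tide
#' phase and moon-horizon position), restricts to individuals whose own
#' orientation was significant, and applies the second-order Rayleigh test to
#' their mean bearings (magnetic frame) and to their alpha_moon values
#' (moon-relative frame) -- the same N individuals in both frames.
#' `prop_significant`, `mean_R` and `sd_R` are computed over all tested
#' (non-excluded) individuals in the stratum. Strata with fewer than 2
#' significant individuals are reported with `insufficient = TRUE` and `NA`
#' summaries. `pool_phases` adds pooled rows (all tide/horizon strata of a
#' phase combined), mirroring a pooled new-moon analysis.
#'
#' @param results list of `individual_result`s.
#' @param by condition keys to stratify on.
#' @param pool_phases character vector of moon-phase labels to add pooled
#'   rows for (e.g. `"new"`).
#' @param sun_frame also summarise bearings relative to the sun azimuth
#'   (supplementary control).
#' @return a data.frame, one row per non-empty condition cell (plus pooled
#'   rows), ordered deterministically.
#' @export
analyze_group <- function(results,
                          by = c("moon_phase", "tide_phase", "moon_above_horizon"),
                          pool_phases = character(0), sun_frame = FALSE) {
  df <- individuals_to_df(results)
  df <- df[!df$excluded, , drop = FALSE]
  if (!nrow(df)) {
    warning("analyze_group: no usable individuals")
    return(NULL)
  }
  cells <- unique(df[, by, drop = FALSE])
  ord <- do.call(order, c(list(factor(cells$moon_phase, levels = PHASE_ORDER)),
                          cells[setdiff(by, "moon_phase")]))
  cells <- cells[ord, , drop = FALSE]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- rep(TRUE, nrow(df))
    for (k in by) sel <- sel & df[[k]] == cells[[k]][i]
    group_row(df[sel, , drop = FALSE], cells[i, , drop = FALSE], sun_frame)
  })
  out <- do.call(rbind, rows)
  for (ph in pool_phases) {
    sel <- df$moon_phase == ph
    if (!any(sel)) {
      warning("pool_phases: no individuals in phase ", ph)
      next
    }
    keys <- cells[1, , drop = FALSE]
    keys[1, ] <- NA
    keys$moon_phase <- ph
    keys$tide_phase <- "pooled"
    pooled <- group_row(df[sel, , drop = FALSE], keys, sun_frame)
    out <- rbind(out, pooled)
  }
  rownames(out) <- NULL
  out
}

#' Swimming-speed contrast between condition strata
#'
#' Splits per-individual mean swimming speeds by a condition key (default:
#' moon above vs below the horizon) and compares the two strata with
#' [rank_sum_test()]. All non-excluded individuals are used (orientation
#' significance is not required for the speed analysis).
#'
#' @param results list of `individual_result`s.
#' @param split condition key with exactly two levels.
#' @return a `rank_test_result`; group 1 is the `TRUE` (or first) level.
#' @export
speed_contrast <- function(results, split = "moon_above_horizon") {
  df <- individuals_to_df(results)
  df <- df[!df$excluded, , drop = FALSE]
  vals <- df[[split]]
  lev <- sort(unique(vals), decreasing = TRUE)  # TRUE first for logical splits
  if (length(lev) < 2) stop("speed_contrast: only one stratum present")
  rank_sum_test(df$mean_speed[vals == lev[1]], df$mean_speed[vals == lev[2]])
}

#' Write the analysis report
#'
#' Writes `group_table.tsv` (the stratified summary), `individuals.tsv` (one
#' row per deployment) and `run_log.txt` (configuration echo) into `out_dir`.
#' Deterministic: identical inputs give byte-identical files.
#'
#' @param groups data.frame from [analyze_group()] (may be `NULL`/empty).
#' @param individuals list of `individual_result`s.
#' @param out_dir output directory, created if needed.
#' @param config named list echoed into the run log.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(groups, individuals, out_dir, config = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gpath <- file.path(out_dir, "group_table.tsv")
  header <- c("moon_phase", "tide_phase", "moon_above_horizon", "n_tested",
              "N", "prop_significant", "mean_R", "sd_R",
              "mag_mean_bearing", "mag_r", "mag_p",
              "moon_mean_bearing", "moon_r", "moon_p")
  if (is.null(groups) || !nrow(groups)) {
    writeLines(paste(header, collapse = "\t"), gpath)
  } else {
    utils::write.table(format(groups, digits = 6, trim = TRUE), gpath,
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  ipath <- file.path(out_dir, "individuals.tsv")
  idf <- individuals_to_df(individuals)
  utils::write.table(format(idf, digits = 6, trim = TRUE), ipath,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  log <- c("discorient run log",
           sprintf("package_version: %s",
                   as.character(utils::packageVersion("discorient"))),
           sprintf("n_individuals: %d", length(individuals)),
           vapply(names(config), function(k) {
             sprintf("%s: %s", k, paste(format(config[[k]]), collapse = " "))
           }, character(1)))
  writeLines(log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' Run the full analysis over a campaign manifest
#'
#' Reads `manifest.csv` (columns `id, track, compass, meta`; paths relative to
#' the manifest), analyses each deployment, and writes the report.
#'
#' @param manifest path to a manifest file.
#' @param out_dir report directory (optional).
#' @param declination magnetic declination passed to every site, degrees east.
#' @param alpha individual significance level.
#' @param pool_phases phases to add pooled rows for (e.g. `"new"`).
#' @param sun_frame repeat the group analysis against the sun azimuth.
#' @return a list with `individuals` and `groups`.
#' @export
analyze_campaign <- function(manifest, out_dir = NULL, declination = 0,
                             alpha = 0.05, pool_phases = character(0),
                             sun_frame = FALSE) {
  man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  base <- dirname(manifest)
  results <- lapply(seq_len(nrow(man)), function(i) {
    md <- read_deployment_meta(file.path(base, man$meta[i]))
    st <- site(md$meta$latitude, md$meta$longitude, declination)
    analyze_individual(read_track(file.path(base, man$track[i]), id = man$id[i]),
                       read_compass(file.path(base, man$compass[i])),
                       md$cal, md$meta, st, alpha = alpha)
  })
  groups <- analyze_group(results, pool_phases = pool_phases,
                          sun_frame = sun_frame)
  if (!is.null(out_dir)) {
    write_report(groups, results, out_dir,
                 config = list(manifest = manifest, declination = declination,
                               alpha = alpha,
                               pool_phases = paste(pool_phases, collapse = ","),
                               sun_frame = sun_frame))
  }
  list(individuals = results, groups = groups)
}
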