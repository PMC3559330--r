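# End-to-end orchestration: generate -> classify -> filter -> dives ->
# currents -> models -> report.

#' Configuration for a full pipeline run
#'
#' Bundles the synthetic-season configuration with every analysis threshold,
#' each defaulting to the value used throughout the study design: 8 km/h
#' maximum sustained swimming speed, 5 m foraging-dive threshold, 150 s
#' dive-location merge window, 0.5 km colony-return radius, 725 m kernel
#' grid cell and a ~3 km (diameter) smoothing kernel.
#'
#' @param seed integer seed driving every stochastic stage.
#' @param sim a [sim_config()]; defaults to `sim_config(seed = seed,
#'   land_fraction = 0.05)`.
#' @param days tide-record length, days.
#' @param constituents tidal constituent set.
#' @param vmax speed-filter threshold, km/h.
#' @param dive_threshold foraging-dive depth threshold, m.
#' @param merge_window dive/location merge window, s.
#' @param trip_radius colony-return radius, km.
#' @param cell KDE grid cell, m.
#' @param bandwidth_m KDE kernel SD, m.
#' @param day_offset station-local day offset, hours.
#' @param dive_fraction fraction of foraging fixes backed by a dive.
#' @param glider_days glider mission length, days.
#' @return object of class `run_config`.
#' @export
pipeline_config <- function(seed = 1L, sim = NULL, days = 28,
                            constituents = default_constituents(),
                            vmax = 8, dive_threshold = 5, merge_window = 150,
                            trip_radius = 0.5, cell = 725,
                            bandwidth_m = 1500, day_offset = -3,
                            dive_fraction = 0.3, glider_days = 21) {
  stopifnot(vmax > 0, dive_threshold > 0, merge_window >= 0,
            trip_radius > 0, cell > 0, bandwidth_m > 0)
  if (is.null(sim)) sim <- sim_config(seed = seed, land_fraction = 0.05)
  structure(list(seed = as.integer(seed), sim = sim, days = days,
                 constituents = constituents, vmax = vmax,
                 dive_threshold = dive_threshold,
                 merge_window = merge_window, trip_radius = trip_radius,
                 cell = cell, bandwidth_m = bandwidth_m,
                 day_offset = day_offset, dive_fraction = dive_fraction,
                 glider_days = glider_days),
            class = "run_config")
}

#' Run the full analysis pipeline on a synthetic season
#'
#' Generates a synthetic season (tides, trips with ARGOS error, 1 Hz dive
#' records, a glider mission under a regime-tied current field, wind),
#' then runs every analysis stage: regime calendar, land-mask and speed
#' filtering, zero-offset correction and dive detection, dive/location
#' merging, trip segmentation, the random-intercept mixed models (regime
#' only, and regime + amplitude + Julian day) on diving-only and on all
#' locations, their likelihood-ratio/AIC comparison, current estimation with
#' the Welch speed test, quadrant fractions and the Mardia-Watson-Wheeler
#' bearing test, the wind/current correlation, and per-regime kernel-density
#' 95% contour areas.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; if given, stage outputs (CSV) and the
#'   report (JSON) are written there.
#' @param quiet suppress per-stage record-count messages.
#' @return a nested report list (also written as JSON when `out_dir` given).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)
  sim <- config$sim
  report <- list(seed = config$seed)

  ## 1. tides and regime calendar
  tide <- gen_tide_series(config$constituents, days = config$days,
                          noise_sd = 0.002, seed = config$seed)
  cal <- build_regime_calendar(tide, day_offset = config$day_offset)
  n_di <- sum(cal$regime == "diurnal")
  n_se <- sum(cal$regime == "semidiurnal")
  say("regimes: ", n_di, " diurnal days, ", n_se, " semidiurnal days")
  if (n_di == 0 || n_se == 0)
    stop("synthetic tide record produced only one regime; extend `days`")
  report$tides <- list(
    n_days = nrow(cal), n_diurnal_days = n_di, n_semidiurnal_days = n_se,
    mean_amplitude_diurnal_m =
      mean(cal$amplitude_m[cal$regime == "diurnal"]),
    mean_amplitude_semidiurnal_m =
      mean(cal$amplitude_m[cal$regime == "semidiurnal"]))

  ## 2. trips + ARGOS error, land mask, speed filter
  tracks <- gen_trips(sim, cal)
  fixes <- as_argos_fixes(tracks$argos)
  n0 <- nrow(fixes)
  fixes <- apply_landmask(fixes, sim$land_polygon)
  n_land <- sum(!fixes$retained)
  fixes <- speed_filter(fixes, vmax = config$vmax)
  n_speed <- sum(fixes$reason == "speed", na.rm = TRUE)
  n_kept <- sum(fixes$retained)
  say("filtering: ", n0, " fixes; ", n_land, " on land, ", n_speed,
      " over ", config$vmax, " km/h; ", n_kept, " retained")
  report$filtering <- list(
    n_fixes = n0, n_rejected_land = n_land, n_rejected_speed = n_speed,
    n_retained = n_kept, pct_removed = 100 * (n0 - n_kept) / n0)

  ## 3. dive records per trip, correction, detection, merging
  retained <- fixes[fixes$retained, ]
  retained$diving <- FALSE
  set.seed(config$seed + 1000)
  n_dive_events <- 0
  for (j in unique(tracks$true$trip)) {
    trip <- tracks$true[tracks$true$trip == j, ]
    # dives accompany a subset of the foraging fixes, just before the fix
    ft <- trip$time[trip$foraging]
    n_dives <- max(1, rbinom(1, length(ft), config$dive_fraction))
    at <- sort(sample(ft, n_dives))
    depths <- runif(n_dives, 10, 80)
    tdr <- gen_dive_record(trip, depths,
                           drift_rate = sim$tdr_drift_m_per_min,
                           seed = config$seed + 2000 + j,
                           dive_starts = at - 120)
    corr <- zero_offset_correct(tdr)
    ev <- detect_dives(corr, threshold = config$dive_threshold)
    n_dive_events <- n_dive_events + nrow(ev)
    sel <- retained$animal_id == trip$animal_id[1] &
      retained$time >= min(trip$time) & retained$time <= max(trip$time)
    if (any(sel)) {
      lab <- merge_dive_locations(retained[sel, ], ev,
                                  window = config$merge_window)
      retained$diving[sel] <- lab$diving
    }
  }
  say("dives: ", n_dive_events, " detected events; ",
      sum(retained$diving), " diving locations, ",
      sum(!retained$diving), " non-diving")
  report$dives <- list(n_events = n_dive_events,
                       n_diving_locations = sum(retained$diving),
                       n_nondiving_locations = sum(!retained$diving))

  ## 4. trips, covariates, mixed models
  trips <- segment_trips(retained, sim$colony_lat, sim$colony_lon,
                         radius = config$trip_radius)
  trips <- label_trip_covariates(trips, cal, config$day_offset)
  say("trips: ", length(unique(trips$trip_id)), " trips, ",
      nrow(trips), " fixes")
  div <- trips[trips$diving, ]
  fits <- list(
    eq1_diving = fit_lmm(div, "eq1", "identity"),
    eq2_diving = fit_lmm(div, "eq2", "identity"),
    eq1_all = fit_lmm(trips, "eq1", "log10"),
    eq2_all = fit_lmm(trips, "eq2", "log10"))
  cmp_div <- compare_models(fits$eq1_diving, fits$eq2_diving)
  cmp_all <- compare_models(fits$eq1_all, fits$eq2_all)
  norm_div <- check_residual_normality(fits$eq1_diving)
  fit_summary <- function(f) list(
    beta = as.list(f$beta), se = as.list(f$se), t = as.list(f$t),
    p = as.list(f$p), sigma_trip = f$sigma_b, sigma_resid = f$sigma_e,
    loglik = f$loglik, aic = f$aic, n_obs = f$n_obs, n_trips = f$n_groups)
  report$models <- list(
    n_trips = length(unique(trips$trip_id)),
    pct_trips_diurnal = 100 * mean(tapply(trips$regime, trips$trip_id,
                                          function(r) r[1]) == "diurnal"),
    mean_dhi_diving_diurnal_km =
      mean(div$dhi_km[div$regime == "diurnal"]),
    mean_dhi_diving_semidiurnal_km =
      mean(div$dhi_km[div$regime == "semidiurnal"]),
    eq1_diving = fit_summary(fits$eq1_diving),
    eq2_diving = fit_summary(fits$eq2_diving),
    eq1_all = fit_summary(fits$eq1_all),
    eq2_all = fit_summary(fits$eq2_all),
    lrt_diving = cmp_div, lrt_all = cmp_all,
    residual_normality_diving = norm_div)

  ## 5. glider currents, regime comparisons, wind
  field <- sim$current_field
  if (is.null(field)) field <- tidal_current_field(cal, config$day_offset)
  wpt_c <- destination_point(sim$colony_lat, sim$colony_lon, 45, 8)
  wpts <- rbind(wpt_c, destination_point(wpt_c$lat, wpt_c$lon, 45, 4))
  segs <- gen_glider_mission(field, wpts, gps_noise_m = 10,
                             seed = config$seed + 1,
                             start = as.POSIXct(min(cal$date),
                                                tz = "UTC") + 12 * 3600,
                             duration_h = config$glider_days * 24)
  cur <- glider_currents(segs, cal, config$day_offset)
  cur <- cur[cur$regime %in% c("diurnal", "semidiurnal"), ]
  sp_d <- cur$speed[cur$regime == "diurnal"]
  sp_s <- cur$speed[cur$regime == "semidiurnal"]
  welch <- compare_speed_regimes(sp_d, sp_s)
  mww <- mww_test(cur$bearing[cur$regime == "diurnal"],
                  cur$bearing[cur$regime == "semidiurnal"],
                  method = "permutation", n_perm = 999,
                  seed = config$seed + 2)
  gof <- vonmises_gof(cur$bearing, n_boot = 99, seed = config$seed + 3)
  wind <- gen_wind_series(start = min(segs$t0),
                          days = config$glider_days, dt_min = 120,
                          seed = config$seed + 4)
  wind_at <- approx(as.numeric(wind$time), wind$speed_mps,
                    xout = as.numeric(cur$t_mid), rule = 2)$y
  wc_d <- correlate_wind_current(wind_at[cur$regime == "diurnal"],
                                 sp_d)
  wc_s <- correlate_wind_current(wind_at[cur$regime == "semidiurnal"],
                                 sp_s)
  say("currents: ", length(sp_d), " diurnal and ", length(sp_s),
      " semidiurnal estimates; Welch t = ", round(welch$t, 2),
      ", MWW W = ", round(mww$W, 2))
  report$currents <- list(
    n_diurnal = length(sp_d), n_semidiurnal = length(sp_s),
    mean_speed_mps = mean(cur$speed),
    mean_speed_diurnal_mps = mean(sp_d),
    mean_speed_semidiurnal_mps = mean(sp_s),
    welch = welch,
    quadrants = as.list(quadrant_fractions(cur$bearing)),
    quadrants_diurnal =
      as.list(quadrant_fractions(cur$bearing[cur$regime == "diurnal"])),
    quadrants_semidiurnal =
      as.list(quadrant_fractions(cur$bearing[cur$regime == "semidiurnal"])),
    mww = list(W = mww$W, p_asymptotic = mww$p_asymptotic,
               p_permutation = mww$p_permutation),
    vonmises_gof = gof,
    wind_correlation_diurnal = wc_d,
    wind_correlation_semidiurnal = wc_s)

  ## 6. utilization contours per regime
  kde_area <- function(sub) {
    surf <- kde_surface(sub, sim$colony_lat, sim$colony_lon,
                        cell = config$cell, bandwidth_m = config$bandwidth_m)
    contour_area_95(surf)
  }
  area_d <- kde_area(trips[trips$regime == "diurnal", ])
  area_s <- kde_area(trips[trips$regime == "semidiurnal", ])
  say("utilization: 95% contour ", round(area_d, 1), " km2 (diurnal) vs ",
      round(area_s, 1), " km2 (semidiurnal)")
  report$utilization <- list(contour_area_diurnal_km2 = area_d,
                             contour_area_semidiurnal_km2 = area_s)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(cal, file.path(out_dir, "regime_calendar.csv"),
              row.names = FALSE)
    write.csv(fixes, file.path(out_dir, "filtered_fixes.csv"),
              row.names = FALSE)
    write.csv(trips, file.path(out_dir, "trip_table.csv"),
              row.names = FALSE)
    write.csv(cur, file.path(out_dir, "current_estimates.csv"),
              row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(report)
}
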