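#' Tidal harmonic constituent
#'
#' @param name constituent label, e.g. "K1".
#' @param amplitude_m amplitude in metres (>= 0).
#' @param period_h period in hours (> 0).
#' @param phase_rad phase in radians.
#' @return one-row data.frame; rows can be bound into a constituent set.
#' @export
tidal_constituent <- function(name, amplitude_m, period_h, phase_rad = 0) {
  if (amplitude_m < 0) stop("amplitude must be >= 0")
  if (period_h <= 0) stop("period must be > 0")
  data.frame(name = as.character(name), amplitude_m = amplitude_m,
             period_h = period_h, phase_rad = phase_rad,
             stringsAsFactors = FALSE)
}

#' Default mixed-tide constituent set
#'
#' Four principal constituents of a mixed, mainly diurnal coastal tide:
#' lunisolar diurnal K1, principal lunar diurnal O1, principal lunar
#' semidiurnal M2 and lunisolar semidiurnal K2. The K1/O1 pair beats on a
#' ~13.7 day cycle against M2, so synthesized series alternate between
#' episodes with one high tide per day and episodes with two, on roughly
#' weekly timescales. The default amplitudes and phases give a season with
#' roughly half its days diurnal, switching in multi-day runs, and daily
#' amplitudes near 1.2 m (diurnal episodes) and 0.8 m (semidiurnal).
#' Amplitudes are configuration, not constants.
#'
#' @param a_k1,a_o1,a_m2,a_k2 constituent amplitudes, metres.
#' @param p_k1,p_o1,p_m2,p_k2 constituent phases, radians.
#' @return data.frame of constituents (see [tidal_constituent()]).
#' @export
default_constituents <- function(a_k1 = 0.61, a_o1 = 0.55,
                                 a_m2 = 0.45, a_k2 = 0.15,
                                 p_k1 = 0, p_o1 = 0,
                                 p_m2 = 1.2, p_k2 = 0.5) {
  rbind(
    tidal_constituent("K1", a_k1, 23.93447, p_k1),
    tidal_constituent("O1", a_o1, 25.81934, p_o1),
    tidal_constituent("M2", a_m2, 12.42060, p_m2),
    tidal_constituent("K2", a_k2, 11.96724, p_k2)
  )
}

#' ARGOS quality classes and default error model
#'
#' Classes 3, 2 and 1 carry stated accuracies (within 100 m, 250 m and
#' 500-1500 m); classes 0, A and B have no error estimate and are given
#' heavy-tailed (t, 3 df) defaults of 1.5, 3 and 10 km scale.
#' @keywords internal
.argos_classes <- c("3", "2", "1", "0", "A", "B")

.default_class_probs <- c(`3` = 0.15, `2` = 0.20, `1` = 0.25,
                          `0` = 0.15, A = 0.15, B = 0.10)

.default_class_error_m <- c(`3` = 100, `2` = 250, `1` = 1000,
                            `0` = 1500, A = 3000, B = 10000)

#' Configuration for the synthetic field season
#'
#' Houses the parameters of the trip generator: the colony location, the
#' per-regime mean foraging distances, the trip random-intercept and residual
#' standard deviations of the distance model, the ARGOS class mix and error
#' scales, TDR drift, and the current field used for glider missions.
#'
#' Distances are generated directly from the statistical model the analysis
#' fits (regime mean + trip intercept + residual), not from a mechanistic
#' movement model.
#'
#' @param seed integer seed; the generator is fully reproducible given the
#'   seed and configuration.
#' @param colony_lat,colony_lon colony coordinates, decimal degrees
#'   (default 64 deg 46 min S, 64 deg 04 min W).
#' @param n_trips number of foraging trips to simulate.
#' @param fixes_per_trip foraging fixes per trip (excludes the colony
#'   departure/return fixes that bound each trip).
#' @param beta_diurnal_km,beta_semidiurnal_km mean foraging distance from the
#'   colony by tidal regime, km.
#' @param sigma_trip_km SD of the per-trip random intercept, km.
#' @param sigma_resid_km residual SD of per-fix distances, km.
#' @param class_probs named probability per ARGOS class; must sum to 1.
#' @param class_error_m named positional error scale per class, metres. For
#'   classes 3/2/1 this is the 95th percentile of a Rayleigh (bivariate
#'   normal) error; for 0/A/B it is the scale of a t(3)-tailed error.
#' @param land_fraction fraction of foraging fixes displaced onto the land
#'   polygon, to exercise masking.
#' @param land_polygon polygon (data.frame lon/lat) used for displacement;
#'   default [toy_island()] 3 km east of the colony.
#' @param fix_interval_min time between successive fixes, minutes. The fix
#'   sampling rate of real tags varies; it is exposed here as configuration.
#' @param n_animals number of birds the trips are spread over (round-robin);
#'   default ~1 bird per 3 trips.
#' @param trip_bearing_deg,trip_bearing_sd mean and SD of per-trip heading.
#' @param fix_bearing_sd within-trip SD of per-fix bearings, degrees.
#' @param tdr_drift_m_per_min TDR pressure-sensor drift rate, m per minute.
#' @param current_field function(time) -> c(u, v) m/s, used by glider runs.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       colony_lat = -64.76667, colony_lon = -64.06667,
                       n_trips = 30L, fixes_per_trip = 22L,
                       beta_diurnal_km = 5.4, beta_semidiurnal_km = 9.1,
                       sigma_trip_km = 1.4, sigma_resid_km = 2.0,
                       class_probs = .default_class_probs,
                       class_error_m = .default_class_error_m,
                       land_fraction = 0,
                       land_polygon = NULL,
                       fix_interval_min = 30,
                       n_animals = NULL,
                       trip_bearing_deg = 45, trip_bearing_sd = 20,
                       fix_bearing_sd = 15,
                       tdr_drift_m_per_min = 0.01,
                       current_field = NULL) {
  if (fixes_per_trip < 1) stop("fixes_per_trip must be >= 1")
  if (sigma_trip_km < 0 || sigma_resid_km < 0)
    stop("standard deviations must be >= 0")
  if (abs(sum(class_probs) - 1) > 1e-8) stop("class_probs must sum to 1")
  if (!all(names(class_probs) %in% .argos_classes))
    stop("class_probs names must be ARGOS classes 3,2,1,0,A,B")
  if (any(class_error_m < 0)) stop("class_error_m must be >= 0")
  if (land_fraction < 0 || land_fraction > 1)
    stop("land_fraction must be in [0, 1]")
  if (is.null(n_animals)) n_animals <- max(1L, as.integer(round(n_trips / 3)))
  if (is.null(land_polygon)) {
    ctr <- destination_point(colony_lat, colony_lon, 90, 3)
    land_polygon <- toy_island(ctr$lat, ctr$lon, radius_km = 0.6)
  }
  structure(list(
    seed = as.integer(seed), colony_lat = colony_lat, colony_lon = colony_lon,
    n_trips = as.integer(n_trips), fixes_per_trip = as.integer(fixes_per_trip),
    beta_diurnal_km = beta_diurnal_km,
    beta_semidiurnal_km = beta_semidiurnal_km,
    sigma_trip_km = sigma_trip_km, sigma_resid_km = sigma_resid_km,
    class_probs = class_probs, class_error_m = class_error_m,
    land_fraction = land_fraction, land_polygon = land_polygon,
    fix_interval_min = fix_interval_min, n_animals = as.integer(n_animals),
    trip_bearing_deg = trip_bearing_deg, trip_bearing_sd = trip_bearing_sd,
    fix_bearing_sd = fix_bearing_sd,
    tdr_drift_m_per_min = tdr_drift_m_per_min,
    current_field = current_field
  ), class = "sim_config")
}
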