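#' Simulate a buoyancy-glider mission under a known current field
#'
#' The glider flies through the water toward its current waypoint at a fixed
#' speed, navigating on its dead-reckoned position. The true position is
#' additionally advected by the current field. At every surfacing the GPS
#' position (true + optional noise) is recorded alongside the dead-reckoned
#' position, and dead reckoning is reset to the GPS fix, as on a real
#' vehicle. The per-segment time-averaged true current is attached as
#' attribute `"true_mean_current"`.
#'
#' The mission is integrated on a planar local grid; each segment's
#' endpoint pair is written back to latitude/longitude on its own local
#' tangent plane, the frame in which dead-reckoning residuals are defined,
#' so segment-scale displacements are represented without projection
#' distortion.
#'
#' @param current_field function(POSIXct) -> c(u, v) in m/s (east, north).
#' @param waypoints data.frame with `lat`, `lon`; visited cyclically.
#' @param speed_through_water glider speed through water, m/s (> 0).
#' @param surfacing_interval_h hours between surfacings (> 0).
#' @param gps_noise_m GPS error SD per axis, metres.
#' @param seed optional integer seed.
#' @param start mission start (POSIXct, UTC).
#' @param duration_h mission length, hours.
#' @param dt_s integration step, seconds.
#' @return data.frame of class `glider_segments` with columns `t0`, `t1`,
#'   `lat_dr`, `lon_dr`, `lat_gps`, `lon_gps`.
#' @export
gen_glider_mission <- function(current_field, waypoints,
                               speed_through_water = 0.3,
                               surfacing_interval_h = 2,
                               gps_noise_m = 0, seed = NULL,
                               start = as.POSIXct("2011-01-10", tz = "UTC"),
                               duration_h = 96, dt_s = 60) {
  if (surfacing_interval_h <= 0) stop("surfacing interval must be > 0")
  if (speed_through_water <= 0)
    stop("zero glider speed: waypoints unreachable")
  if (!is.null(seed)) set.seed(seed)

  olat <- waypoints$lat[1]; olon <- waypoints$lon[1]
  wp <- project_aeqd(waypoints$lat, waypoints$lon, olat, olon)
  n_seg <- floor(duration_h / surfacing_interval_h)
  seg_len <- round(surfacing_interval_h * 3600 / dt_s)

  pos <- wp[1, ]           # true position (m, local plane)
  dr <- pos                # dead-reckoned position
  iw <- if (nrow(wp) > 1) 2L else 1L
  t <- 0
  out <- vector("list", n_seg)
  truth <- matrix(NA_real_, n_seg, 2)

  for (s in seq_len(n_seg)) {
    t0 <- t
    dr <- pos  # reset dead reckoning at the (noise-free) surfacing point
    cur_sum <- c(0, 0)
    for (k in seq_len(seg_len)) {
      tow <- wp[iw, ] - dr
      dwp <- sqrt(sum(tow^2))
      if (dwp < 200) {
        iw <- if (iw >= nrow(wp)) 1L else iw + 1L
        tow <- wp[iw, ] - dr
        dwp <- sqrt(sum(tow^2))
      }
      u_hat <- if (dwp > 0) tow / dwp else c(0, 0)
      cur <- current_field(start + t)
      dr <- dr + u_hat * speed_through_water * dt_s
      pos <- pos + (u_hat * speed_through_water + cur) * dt_s
      cur_sum <- cur_sum + cur
      t <- t + dt_s
    }
    gps <- pos
    if (gps_noise_m > 0) gps <- gps + rnorm(2, 0, gps_noise_m)
    # encode the segment's endpoint pair on its own local tangent plane
    # (shared cosine-latitude scaling), the frame in which dead-reckoning
    # residuals are defined
    rad <- pi / 180
    lat_dr <- olat + dr[2] / (.EARTH_RADIUS_KM * 1000) / rad
    lat_gps <- olat + gps[2] / (.EARTH_RADIUS_KM * 1000) / rad
    cos_c <- cos((lat_dr + lat_gps) / 2 * rad)
    lon_dr <- olon + dr[1] / (.EARTH_RADIUS_KM * 1000 * cos_c) / rad
    lon_gps <- olon + gps[1] / (.EARTH_RADIUS_KM * 1000 * cos_c) / rad
    out[[s]] <- data.frame(t0 = start + t0, t1 = start + t,
                           lat_dr = lat_dr, lon_dr = lon_dr,
                           lat_gps = lat_gps, lon_gps = lon_gps)
    truth[s, ] <- cur_sum / seg_len
  }
  segs <- do.call(rbind, out)
  class(segs) <- c("glider_segments", "data.frame")
  attr(segs, "true_mean_current") <- truth
  segs
}

#' Tidal current field tied to a regime calendar
#'
#' Builds a deterministic current field for glider simulations: flow along a
#' principal axis toward `bearing_deg`, steady (never reversing) with a
#' diurnal-period modulation on diurnal-regime days, and oscillating at the
#' M2 period with reversals on semidiurnal days. Small incommensurate
#' sinusoids add cross-axis structure so bearings spread around the axis.
#'
#' @param calendar regime calendar (see [build_regime_calendar()]).
#' @param day_offset station-local day offset, hours.
#' @param bearing_deg principal flow direction, degrees clockwise from north.
#' @param diurnal_mean,diurnal_osc mean and modulation amplitude of the
#'   along-axis speed on diurnal days, m/s (mean > osc: no reversal).
#' @param semidiurnal_mean,semidiurnal_osc same for semidiurnal days
#'   (osc > mean: the flow reverses over a tidal cycle).
#' @param eddy_mps amplitude of the incommensurate perturbations, m/s.
#' @return function(POSIXct) -> c(u, v) m/s.
#' @export
tidal_current_field <- function(calendar, day_offset = -3, bearing_deg = 45,
                                diurnal_mean = 0.14, diurnal_osc = 0.11,
                                semidiurnal_mean = 0.08,
                                semidiurnal_osc = 0.15,
                                eddy_mps = 0.06) {
  reg <- calendar$regime
  names(reg) <- as.character(calendar$date)
  br <- bearing_deg * pi / 180
  ax <- c(sin(br), cos(br))
  cx <- c(cos(br), -sin(br))
  function(time) {
    th <- as.numeric(time) / 3600
    d <- as.character(as.Date(time + day_offset * 3600, tz = "UTC"))
    r <- reg[d]
    if (is.na(r)) r <- "semidiurnal"
    s <- if (r == "diurnal") {
      diurnal_mean + diurnal_osc * sin(2 * pi * th / 23.93447)
    } else {
      semidiurnal_mean + semidiurnal_osc * sin(2 * pi * th / 12.4206)
    }
    e1 <- eddy_mps * sin(2 * pi * th / 7.37 + 1.1)
    e2 <- eddy_mps * sin(2 * pi * th / 16.91 + 2.3)
    s * ax + e1 * cx + e2 * ax * 0.5
  }
}
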