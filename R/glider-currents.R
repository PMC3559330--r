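# Depth-integrated currents from glider dead-reckoning residuals, and the
# regime comparisons built on them.

#' Estimate depth-integrated current for glider segments
#'
#' The current is the displacement between where the glider surfaced (GPS)
#' and where its internal navigation believed it was (dead reckoning),
#' divided by the segment duration. The displacement is taken on a local
#' tangent plane (equirectangular with cosine-latitude scaling) at the
#' segment midpoint; at segment scales of a few km the spherical correction
#' is negligible.
#'
#' @param segments a `glider_segments` table (`t0`, `t1`, `lat_dr`,
#'   `lon_dr`, `lat_gps`, `lon_gps`), or vectors via the other arguments.
#' @param calendar optional regime calendar; if given, each estimate is
#'   labeled by the regime at the segment's midpoint time.
#' @param day_offset hours, as in [assign_regime()].
#' @return data.frame of class `current_estimates`: `t_mid`, `u`, `v` (m/s,
#'   east/north), `speed` (m/s), `bearing` (degrees clockwise from north,
#'   direction toward), and `regime`/`amplitude_m` when a calendar is given.
#' @export
glider_currents <- function(segments, calendar = NULL, day_offset = -3) {
  dur <- as.numeric(difftime(segments$t1, segments$t0, units = "secs"))
  est <- estimate_segment_current(segments$lat_dr, segments$lon_dr,
                                  segments$lat_gps, segments$lon_gps, dur)
  est$t_mid <- segments$t0 + dur / 2
  est <- est[, c("t_mid", "u", "v", "speed", "bearing")]
  if (!is.null(calendar)) {
    lab <- assign_regime(est$t_mid, calendar, day_offset)
    est$regime <- lab$regime
    est$amplitude_m <- lab$amplitude_m
  }
  class(est) <- c("current_estimates", "data.frame")
  est
}

#' @rdname glider_currents
#' @param lat_dr,lon_dr dead-reckoned surfacing position(s).
#' @param lat_gps,lon_gps GPS surfacing position(s).
#' @param duration_s segment duration(s), seconds (> 0).
#' @export
estimate_segment_current <- function(lat_dr, lon_dr, lat_gps, lon_gps,
                                     duration_s) {
  if (any(duration_s <= 0)) stop("duration must be > 0")
  .check_coords(lat_dr, lon_dr)
  .check_coords(lat_gps, lon_gps)
  rad <- pi / 180
  lat_mid <- (lat_dr + lat_gps) / 2
  dx <- (lon_gps - lon_dr) * rad * cos(lat_mid * rad) *
    .EARTH_RADIUS_KM * 1000
  dy <- (lat_gps - lat_dr) * rad * .EARTH_RADIUS_KM * 1000
  u <- dx / duration_s
  v <- dy / duration_s
  data.frame(u = u, v = v, speed = sqrt(u^2 + v^2),
             bearing = (atan2(u, v) / rad) %% 360)
}

#' Fraction of bearings per compass quadrant
#'
#' Quadrants are NE = \[0, 90), SE = \[90, 180), SW = \[180, 270),
#' NW = \[270, 360), in degrees clockwise from north.
#'
#' @param bearings bearings in degrees (any real; reduced mod 360).
#' @return named numeric vector (NE, SE, SW, NW) summing to 1.
#' @export
quadrant_fractions <- function(bearings) {
  if (length(bearings) == 0) stop("empty bearing list")
  q <- floor((bearings %% 360) / 90) + 1
  counts <- tabulate(q, nbins = 4)
  stats::setNames(counts / length(bearings), c("NE", "SE", "SW", "NW"))
}

#' Welch two-sample comparison of current speeds
#'
#' Two-sided Welch t-test (unequal variances, Welch-Satterthwaite fractional
#' degrees of freedom) of mean current speed between two regimes.
#'
#' @param speeds_a,speeds_b numeric vectors (each length >= 2).
#' @return list (`t`, `df`, `p`, `mean_a`, `mean_b`).
#' @export
compare_speed_regimes <- function(speeds_a, speeds_b) {
  if (length(speeds_a) < 2 || length(speeds_b) < 2)
    stop("each group needs at least 2 observations")
  if (var(speeds_a) == 0 && var(speeds_b) == 0) {
    if (mean(speeds_a) == mean(speeds_b))
      return(list(t = 0, df = length(speeds_a) + length(speeds_b) - 2, p = 1,
                  mean_a = mean(speeds_a), mean_b = mean(speeds_b)))
    stop("degenerate zero-variance groups")
  }
  ht <- t.test(speeds_a, speeds_b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_a = mean(speeds_a), mean_b = mean(speeds_b))
}

#' Correlation between wind speed and current speed
#'
#' Pearson correlation on paired series with the usual t-test:
#' `t = r * sqrt(df / (1 - r^2))`, df = n - 2, two-sided p.
#'
#' @param wind,current equal-length paired numeric vectors, n >= 3.
#' @return list (`r`, `t`, `df`, `p`).
#' @export
correlate_wind_current <- function(wind, current) {
  if (length(wind) != length(current)) stop("series must be paired")
  if (length(wind) < 3) stop("need n >= 3")
  if (sd(wind) == 0 || sd(current) == 0) stop("constant series")
  ct <- cor.test(wind, current, method = "pearson")
  list(r = unname(ct$estimate), t = unname(ct$statistic),
       df = unname(ct$parameter), p = ct$p.value)
}
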