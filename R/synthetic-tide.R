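#' Synthesize a tide-gauge series from harmonic constituents
#'
#' Sea-level height is the sum of cosine constituents,
#' `h(t) = sum_c A_c * cos(2*pi*t/T_c - phi_c) + eps(t)`, sampled on a
#' regular grid. With a mixed constituent set (see [default_constituents()])
#' the series alternates between one-high-per-day and two-highs-per-day
#' episodes as the diurnal pair beats against the semidiurnal pair.
#'
#' @param constituents data.frame of constituents ([tidal_constituent()]).
#' @param start first timestamp (POSIXct, UTC).
#' @param days length of the record in days (>= 1).
#' @param dt sampling interval in minutes; must divide 24 h evenly.
#' @param noise_sd gauge noise SD, metres.
#' @param seed optional integer seed for the noise.
#' @return data.frame of class `tide_series` with columns `time`, `height_m`.
#' @export
gen_tide_series <- function(constituents,
                            start = as.POSIXct("2011-01-05", tz = "UTC"),
                            days = 30, dt = 6, noise_sd = 0, seed = NULL) {
  if (is.null(constituents) || nrow(constituents) == 0)
    stop("constituent list must be non-empty")
  if (dt <= 0) stop("dt must be positive")
  if (1440 %% dt != 0) stop("dt must divide 24 hours evenly")
  if (days < 1) stop("days must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  t_min <- seq(0, days * 1440 - dt, by = dt)
  hours <- t_min / 60
  h <- rep(0, length(hours))
  for (i in seq_len(nrow(constituents))) {
    h <- h + constituents$amplitude_m[i] *
      cos(2 * pi * hours / constituents$period_h[i] -
            constituents$phase_rad[i])
  }
  if (noise_sd > 0) h <- h + rnorm(length(h), 0, noise_sd)
  out <- data.frame(time = start + t_min * 60, height_m = h)
  class(out) <- c("tide_series", "data.frame")
  out
}

#' Synthesize a wind-speed series
#'
#' Independent positive wind speeds (truncated normal), used to check that
#' wind is uncorrelated with depth-integrated currents.
#'
#' @param start first timestamp (POSIXct, UTC).
#' @param days record length, days.
#' @param dt_min sampling interval, minutes.
#' @param mean_mps,sd_mps wind speed mean and SD, m/s.
#' @param seed optional integer seed.
#' @return data.frame with columns `time`, `speed_mps`.
#' @export
gen_wind_series <- function(start = as.POSIXct("2011-01-05", tz = "UTC"),
                            days = 30, dt_min = 60,
                            mean_mps = 4, sd_mps = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t_min <- seq(0, days * 1440 - dt_min, by = dt_min)
  sp <- pmax(0.1, rnorm(length(t_min), mean_mps, sd_mps))
  data.frame(time = start + t_min * 60, speed_mps = sp)
}
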