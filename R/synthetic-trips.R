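#' Simulate central-place foraging trips and their ARGOS fixes
#'
#' Trips are distance-draw constructs matching the statistical model the
#' pipeline fits: per-fix true distance from the colony is
#' `beta(regime) + b_trip + eps`, with `b_trip ~ N(0, sigma_trip^2)` and
#' `eps ~ N(0, sigma_resid^2)`. Each trip departs from and returns to the
#' colony (boundary fixes at the colony itself), and trips are scheduled one
#' per day across the calendar, cycling through the birds round-robin.
#' ARGOS fixes are the true positions plus class-dependent error: Rayleigh
#' (bivariate normal) error scaled so 97.5% of fixes fall within the stated
#' class accuracy for classes 3/2/1 (comfortably inside the "accurate
#' within" wording), and heavy-tailed t(3) error for classes 0/A/B. A configurable fraction of foraging fixes is displaced onto the
#' land polygon to exercise masking.
#'
#' True distances are truncated below at `radius + 0.1` km (radius = 0.5) so
#' that foraging fixes stay outside the colony-return radius; with the
#' default parameters this affects ~2% of draws.
#'
#' @param config a [sim_config()].
#' @param calendar a regime calendar (data.frame with `date`, `regime`,
#'   `amplitude_m`) covering the simulated span.
#' @return list with elements `true` (true track, including true distance
#'   `d_true_km` and `foraging` flag) and `argos` (id, time, lat, lon,
#'   quality), both sorted by animal and time.
#' @export
gen_trips <- function(config, calendar) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_trips < 1) stop("zero trips requested")
  usable <- calendar[calendar$regime %in% c("diurnal", "semidiurnal"), ]
  if (nrow(usable) == 0) stop("calendar has no classified days")
  set.seed(config$seed)

  m <- config$fixes_per_trip
  dates <- usable$date[((seq_len(config$n_trips) - 1) %% nrow(usable)) + 1]
  true_list <- vector("list", config$n_trips)
  for (j in seq_len(config$n_trips)) {
    day <- usable[usable$date == dates[j], ]
    if (nrow(day) != 1) stop("calendar gap overlapping a trip")
    regime <- as.character(day$regime)
    beta <- if (regime == "diurnal") config$beta_diurnal_km else
      config$beta_semidiurnal_km
    b_j <- rnorm(1, 0, config$sigma_trip_km)
    d <- beta + b_j + rnorm(m, 0, config$sigma_resid_km)
    d <- pmax(d, 0.6)
    head_j <- rnorm(1, config$trip_bearing_deg, config$trip_bearing_sd)
    brg <- head_j + rnorm(m, 0, config$fix_bearing_sd)
    pos <- destination_point(config$colony_lat, config$colony_lon, brg, d)
    t0 <- as.POSIXct(dates[j], tz = "UTC") + 8 * 3600 +
      round(runif(1, 0, 2 * 3600))
    times <- t0 + (0:(m + 1)) * config$fix_interval_min * 60
    true_list[[j]] <- data.frame(
      animal_id = sprintf("bird%02d", ((j - 1) %% config$n_animals) + 1),
      trip = j,
      time = times,
      lat = c(config$colony_lat, pos$lat, config$colony_lat),
      lon = c(config$colony_lon, pos$lon, config$colony_lon),
      d_true_km = c(0, d, 0),
      regime = regime,
      foraging = c(FALSE, rep(TRUE, m), FALSE),
      stringsAsFactors = FALSE
    )
  }
  true <- do.call(rbind, true_list)

  n <- nrow(true)
  quality <- sample(names(config$class_probs), n, replace = TRUE,
                    prob = config$class_probs)
  scale_m <- unname(config$class_error_m[quality])
  heavy <- quality %in% c("0", "A", "B")
  # Rayleigh: 97.5% of radial errors within scale -> axis sd = scale / 2.716
  sd_m <- scale_m / sqrt(2 * log(40))
  ex <- ifelse(heavy, scale_m * rt(n, df = 3) / 3, rnorm(n, 0, sd_m))
  ey <- ifelse(heavy, scale_m * rt(n, df = 3) / 3, rnorm(n, 0, sd_m))
  err_km <- sqrt(ex^2 + ey^2) / 1000
  err_brg <- (atan2(ex, ey) * 180 / pi) %% 360
  obs <- destination_point(true$lat, true$lon, err_brg, err_km)

  if (config$land_fraction > 0) {
    cand <- which(true$foraging)
    n_land <- round(config$land_fraction * length(cand))
    if (n_land > 0) {
      onto <- sample(cand, n_land)
      poly <- config$land_polygon
      ctr_lon <- mean(poly$lon[-nrow(poly)])
      ctr_lat <- mean(poly$lat[-nrow(poly)])
      jit <- runif(n_land, 0, 0.15)
      jbr <- runif(n_land, 0, 360)
      p <- destination_point(ctr_lat, ctr_lon, jbr, jit)
      obs$lat[onto] <- p$lat
      obs$lon[onto] <- p$lon
    }
  }

  argos <- data.frame(animal_id = true$animal_id, time = true$time,
                      lat = obs$lat, lon = obs$lon, quality = quality,
                      stringsAsFactors = FALSE)
  ord <- order(argos$animal_id, argos$time)
  list(true = true[ord, ], argos = argos[ord, ])
}

#' Build a regime calendar directly (for simulations)
#'
#' @param dates Date vector.
#' @param regime character vector, recycled ("diurnal"/"semidiurnal").
#' @param amplitude_m daily tidal amplitude, metres, recycled.
#' @return regime-calendar data.frame.
#' @export
make_calendar <- function(dates, regime, amplitude_m = 1) {
  data.frame(date = dates,
             regime = rep_len(as.character(regime), length(dates)),
             n_high_tides = ifelse(
               rep_len(as.character(regime), length(dates)) == "diurnal", 1L, 2L),
             amplitude_m = rep_len(amplitude_m, length(dates)),
             stringsAsFactors = FALSE)
}
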