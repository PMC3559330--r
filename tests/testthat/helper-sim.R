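# Shared simulation helpers for the tests.

# Trip-table data generated from the distance model via the package
# generator (error-free ARGOS so distances are exact), labeled with an
# alternating-regime calendar.
sim_trip_data <- function(n_trips, beta_d = 5.4, beta_s = 9.1,
                          sigma_b = 1.4, sigma_e = 2,
                          fixes_per_trip = 20, seed = 1) {
  set.seed(seed * 7919 + 13)
  cal <- make_calendar(
    seq(as.Date("2011-01-05"), by = "day", length.out = n_trips),
    rep(c("diurnal", "semidiurnal"), length.out = n_trips),
    amplitude_m = round(runif(n_trips, 0.6, 1.5), 2))
  cfg <- sim_config(seed = seed, n_trips = n_trips,
                    fixes_per_trip = fixes_per_trip,
                    beta_diurnal_km = beta_d, beta_semidiurnal_km = beta_s,
                    sigma_trip_km = sigma_b, sigma_resid_km = sigma_e,
                    class_probs = c(`3` = 1), class_error_m = c(`3` = 0))
  tr <- gen_trips(cfg, cal)
  trips <- segment_trips(tr$argos, cfg$colony_lat, cfg$colony_lon)
  label_trip_covariates(trips, cal)
}

# A short track along a parallel at constant slow speed, with optional
# spike fixes displaced far off-path.
make_toy_track <- function(n = 20, speed_kmh = 2, step_h = 1,
                           quality = "1", spike_at = integer(0),
                           spike_km = 40, animal = "a1") {
  lat0 <- -64.8
  step_km <- speed_kmh * step_h
  lons <- -64 + (seq_len(n) - 1) * step_km /
    (great_circle_distance(lat0, -64, lat0, -63) / 1)  # km per deg lon
  d <- data.frame(
    animal_id = animal,
    time = as.POSIXct("2011-01-10", tz = "UTC") + (seq_len(n) - 1) * step_h * 3600,
    lat = lat0, lon = lons,
    quality = rep_len(quality, n), stringsAsFactors = FALSE)
  for (i in spike_at) {
    p <- destination_point(d$lat[i], d$lon[i], 0, spike_km)
    d$lat[i] <- p$lat; d$lon[i] <- p$lon
  }
  d
}

# The printed 12-row, 3-trip toy dataset used for likelihood checks.
toy_trip_fixture <- function() {
  path <- system.file("extdata", "trips_toy.csv", package = "tideforage")
  d <- read.csv(path, stringsAsFactors = FALSE)
  d$time <- as.POSIXct(d$time, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  d
}
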