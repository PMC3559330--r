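test_that("tide synthesis follows the harmonic sum and peak structure", {
  # single 24 h constituent, peaks placed mid-day: one maximum per day
  cs <- tidal_constituent("D1", 1, 24, phase_rad = pi)
  s <- gen_tide_series(cs, days = 3, dt = 6, noise_sd = 0)
  highs <- detect_high_tides(s)
  expect_length(highs, 3)
  expect_equal(as.numeric(diff(highs), units = "hours"), c(24, 24))

  # closed-form check of heights
  hours <- as.numeric(s$time - s$time[1], units = "hours")
  expect_equal(s$height_m, cos(2 * pi * hours / 24 - pi), tolerance = 1e-12)

  # single M2-period constituent: >= 2 maxima on >= 9 of 10 days
  s2 <- gen_tide_series(tidal_constituent("M2", 1, 12.4206, pi), days = 10,
                        noise_sd = 0)
  counts <- oracle_daily_high_count(s2, unique(as.Date(s2$time, tz = "UTC")),
                                    day_offset = 0)
  expect_gte(sum(counts >= 2), 9)
})

test_that("mixed diurnal/semidiurnal constituents alternate in multi-day runs", {
  cs <- rbind(tidal_constituent("K1", 0.5, 23.93447),
              tidal_constituent("O1", 0.45, 25.81934),
              tidal_constituent("M2", 0.3, 12.4206))
  s <- gen_tide_series(cs, days = 30, noise_sd = 0)
  cal <- build_regime_calendar(s)
  runs <- rle(cal$regime)
  expect_gte(max(runs$lengths[runs$values == "diurnal"]), 3)
  expect_gte(max(runs$lengths[runs$values == "semidiurnal"]), 3)
})

test_that("tide generator validates inputs", {
  expect_error(gen_tide_series(default_constituents()[0, ]), "non-empty")
  expect_error(gen_tide_series(default_constituents(), dt = -5), "positive")
  expect_error(gen_tide_series(default_constituents(), dt = 7), "divide")
})

test_that("noiseless trips place every foraging fix at the regime mean", {
  cal <- make_calendar(seq(as.Date("2011-01-05"), by = "day",
                           length.out = 6),
                       rep(c("diurnal", "semidiurnal"), 3))
  cfg <- sim_config(seed = 3, n_trips = 6, fixes_per_trip = 8,
                    beta_diurnal_km = 5.4, beta_semidiurnal_km = 9.1,
                    sigma_trip_km = 0, sigma_resid_km = 0,
                    class_probs = c(`3` = 1), class_error_m = c(`3` = 0))
  tr <- gen_trips(cfg, cal)
  d <- great_circle_distance(tr$argos$lat, tr$argos$lon,
                             cfg$colony_lat, cfg$colony_lon)
  f <- tr$true$foraging
  expect_equal(as.numeric(tapply(d[f], tr$true$regime[f], mean)),
               c(5.4, 9.1), tolerance = 1e-9)
  expect_true(all(abs(d[f & tr$true$regime == "diurnal"] - 5.4) < 1e-9))
  # boundary fixes return to within 0.5 km of the colony
  expect_true(all(d[!f] < 0.5))
})

test_that("class-3 ARGOS error is within 100 m for >= 95% of fixes", {
  cal <- make_calendar(seq(as.Date("2011-01-05"), by = "day",
                           length.out = 25), "semidiurnal")
  cfg <- sim_config(seed = 11, n_trips = 25, fixes_per_trip = 40,
                    sigma_trip_km = 0, sigma_resid_km = 0,
                    class_probs = c(`3` = 1), class_error_m = c(`3` = 100))
  tr <- gen_trips(cfg, cal)
  err_m <- 1000 * great_circle_distance(tr$true$lat, tr$true$lon,
                                        tr$argos$lat, tr$argos$lon)
  expect_gte(length(err_m), 1000)
  expect_gte(mean(err_m <= 100), 0.95)
})

test_that("the generator is deterministic given seed and config", {
  cal <- make_calendar(seq(as.Date("2011-01-05"), by = "day",
                           length.out = 8),
                       rep(c("diurnal", "semidiurnal"), 4))
  cfg <- sim_config(seed = 9, n_trips = 8, land_fraction = 0.1)
  a <- gen_trips(cfg, cal)
  b <- gen_trips(cfg, cal)
  expect_identical(a, b)
  s1 <- gen_tide_series(default_constituents(), days = 3, noise_sd = 0.01,
                        seed = 5)
  s2 <- gen_tide_series(default_constituents(), days = 3, noise_sd = 0.01,
                        seed = 5)
  expect_identical(s1, s2)
})

test_that("trip generator rejects bad inputs", {
  cal <- make_calendar(as.Date("2011-01-05"), "diurnal")
  expect_error(sim_config(n_trips = 5, fixes_per_trip = 0), "fixes_per_trip")
  expect_error(sim_config(class_probs = c(`3` = 0.5)), "sum to 1")
  expect_error(gen_trips(sim_config(n_trips = 3),
                         make_calendar(as.Date(character()), character())),
               "no classified days")
})

test_that("dive records superimpose square dives on linear drift", {
  span <- as.POSIXct(c("2011-01-10 08:00:00", "2011-01-10 09:00:00"),
                     tz = "UTC")
  # drift 0, one dive to 20 m: surface reads 0, dive reads 20
  s <- gen_dive_record(span, dive_depths = 20, drift_rate = 0,
                       noise_sd = 0, dive_duration_s = 60)
  log <- attr(s, "dive_log")
  expect_equal(nrow(log), 1)
  in_dive <- s$time >= log$start & s$time <= log$end
  expect_true(all(s$depth_m[in_dive] == 20))
  expect_true(all(s$depth_m[!in_dive] == 0))
  expect_equal(sum(in_dive), 60)

  # drift 0.01 m/min over 10 h: final surface reading 6 m
  span10 <- as.POSIXct(c("2011-01-10 00:00:00", "2011-01-10 10:00:00"),
                       tz = "UTC")
  s2 <- gen_dive_record(span10, dive_depths = numeric(0), drift_rate = 0.01,
                        noise_sd = 0)
  expect_equal(tail(s2$depth_m, 1), 6, tolerance = 1e-9)
  # no dives: the record never exceeds the drift envelope
  expect_lte(max(s2$depth_m), 6)
  expect_equal(nrow(attr(s2, "dive_log")), 0)
})

test_that("dive record validates depths and span", {
  span <- as.POSIXct(c("2011-01-10 08:00:00", "2011-01-10 09:00:00"),
                     tz = "UTC")
  expect_error(gen_dive_record(span, dive_depths = -3), "positive")
  expect_error(gen_dive_record(rev(span), dive_depths = 10), "positive")
})

test_that("glider mission separates dead-reckoned and GPS positions by the current integral", {
  wpts <- data.frame(lat = c(-64.7, -64.60), lon = c(-64.2, -64.0))
  # zero current, no GPS noise: positions coincide
  still <- function(t) c(0, 0)
  m0 <- gen_glider_mission(still, wpts, speed_through_water = 0.3,
                           surfacing_interval_h = 2, duration_h = 12)
  expect_equal(m0$lat_dr, m0$lat_gps, tolerance = 1e-12)
  expect_equal(m0$lon_dr, m0$lon_gps, tolerance = 1e-12)

  # constant 0.1 m/s eastward current, 2 h segments: GPS 720 m east of DR
  east <- function(t) c(0.1, 0)
  m1 <- gen_glider_mission(east, wpts, surfacing_interval_h = 2,
                           duration_h = 8)
  dx <- great_circle_distance(m1$lat_dr, m1$lon_dr,
                              m1$lat_dr, m1$lon_gps) * 1000
  expect_equal(dx, rep(720, nrow(m1)), tolerance = 1)
  expect_equal(m1$lat_gps, m1$lat_dr, tolerance = 1e-7)

  # sinusoidal current: per-segment displacement matches the analytic
  # integral within 1%
  period_s <- 12.42 * 3600
  t0 <- as.POSIXct("2011-01-10", tz = "UTC")
  sine <- function(t) c(0.2 * sin(2 * pi * as.numeric(t - t0, units = "secs")
                                  / period_s), 0)
  m2 <- gen_glider_mission(sine, wpts, surfacing_interval_h = 2,
                           duration_h = 12, start = t0, dt_s = 60)
  est <- estimate_segment_current(m2$lat_dr, m2$lon_dr, m2$lat_gps,
                                  m2$lon_gps,
                                  as.numeric(m2$t1 - m2$t0, units = "secs"))
  a <- as.numeric(m2$t0 - t0, units = "secs")
  b <- as.numeric(m2$t1 - t0, units = "secs")
  w <- 2 * pi / period_s
  analytic_u <- 0.2 * (cos(w * a) - cos(w * b)) / (w * (b - a))
  expect_equal(est$u, analytic_u, tolerance = 0.01)
  expect_error(gen_glider_mission(still, wpts, speed_through_water = 0),
               "unreachable")
})

test_that("synthetic data set round-trips through its CSV formats", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 4, n_trips = 4, fixes_per_trip = 5)
  paths <- write_synthetic_set(cfg, dir, days = 16)
  expect_true(all(file.exists(unlist(paths))))
  tide <- read_tide_csv(paths$tide)
  expect_s3_class(tide, "tide_series")
  expect_true(nrow(tide) == 16 * 240)
  fixes <- read_argos_csv(paths$argos)
  expect_true(all(fixes$quality %in% c("3", "2", "1", "0", "A", "B")))
  mask <- read_landmask(paths$landmask)
  expect_equal(nrow(mask[[1]]), nrow(cfg$land_polygon))
  expect_equal(mask[[1]]$lon, cfg$land_polygon$lon, tolerance = 1e-9)
  tdr <- read_tdr_csv(paths$tdr)
  expect_false(attr(tdr, "corrected"))
  glider <- read_glider_csv(paths$glider)
  expect_s3_class(glider$t0, "POSIXct")
  manifest <- jsonlite::read_json(paths$manifest)
  expect_equal(manifest$seed, 4)
})
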