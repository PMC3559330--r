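test_that("haversine distance matches closed forms and stays metric", {
  expect_equal(great_circle_distance(10, 20, 10, 20), 0)
  # one degree of meridian arc: 2*pi*R/360
  expect_equal(great_circle_distance(0, 0, 1, 0), 111.195, tolerance = 0.01)
  # symmetric
  expect_equal(great_circle_distance(-64.8, -64, 12, 33),
               great_circle_distance(12, 33, -64.8, -64))
  # triangle inequality over random triples
  set.seed(5)
  for (k in 1:1000) {
    lat <- runif(3, -89, 89); lon <- runif(3, -180, 180)
    ab <- great_circle_distance(lat[1], lon[1], lat[2], lon[2])
    bc <- great_circle_distance(lat[2], lon[2], lat[3], lon[3])
    ac <- great_circle_distance(lat[1], lon[1], lat[3], lon[3])
    if (ac > ab + bc + 1e-9) fail("triangle inequality violated")
  }
  succeed()
  expect_error(great_circle_distance(91, 0, 0, 0), "invalid")
})

test_that("haversine agrees with an independent geodesy library", {
  skip_if_not_installed("geosphere")
  set.seed(6)
  lat <- runif(50, -80, 80); lon <- runif(50, -180, 180)
  ours <- great_circle_distance(lat[-50], lon[-50], lat[-1], lon[-1])
  ref <- geosphere::distHaversine(cbind(lon[-50], lat[-50]),
                                  cbind(lon[-1], lat[-1]),
                                  r = 6371008.8) / 1000
  expect_equal(ours, ref, tolerance = 1e-9)
})

test_that("land masking rejects interior points and keeps offshore ones", {
  island <- toy_island(-64.75, -64.0, radius_km = 1)
  fixes <- as_argos_fixes(data.frame(
    animal_id = "a1",
    time = as.POSIXct("2011-01-10", tz = "UTC") + (0:1) * 3600,
    lat = c(-64.75, -64.70), lon = c(-64.0, -63.8),
    quality = c("1", "1"), stringsAsFactors = FALSE))
  out <- apply_landmask(fixes, island)
  expect_false(out$retained[1])  # centroid
  expect_equal(out$reason[1], "land")
  expect_true(out$retained[2])   # offshore
})

test_that("point-in-polygon agrees with a ray-casting oracle on random points", {
  # concave polygon to exercise the even-odd rule
  poly <- data.frame(lon = c(0, 4, 4, 2, 2, 0, 0),
                     lat = c(0, 0, 3, 3, 1, 1, 0))
  set.seed(7)
  px <- runif(1000, -1, 5); py <- runif(1000, -1, 4)
  fixes <- as_argos_fixes(data.frame(
    animal_id = "a1",
    time = as.POSIXct("2011-01-10", tz = "UTC") + seq_len(1000),
    lat = py, lon = px, quality = "1", stringsAsFactors = FALSE))
  out <- apply_landmask(fixes, poly)
  want_inside <- mapply(oracle_point_in_polygon, fixes$lon, fixes$lat,
                        MoreArgs = list(poly = poly))
  expect_equal(!out$retained, unname(want_inside))
  # boundary points are retained
  bfix <- as_argos_fixes(data.frame(
    animal_id = "a1", time = as.POSIXct("2011-01-10", tz = "UTC"),
    lat = 0, lon = 2, quality = "1", stringsAsFactors = FALSE))
  expect_true(apply_landmask(bfix, poly)$retained)
})

test_that("speed filter removes spikes and nothing else on clean tracks", {
  # two fixes, 1 km / 1 h apart: both retained
  two <- speed_filter(as_argos_fixes(make_toy_track(n = 2, speed_kmh = 1)))
  expect_true(all(two$retained))

  # straight 2 km/h track with one 40 km spike: exactly the spike removed
  tr <- make_toy_track(n = 15, speed_kmh = 2, spike_at = 8)
  out <- speed_filter(as_argos_fixes(tr))
  expect_equal(which(!out$retained), 8)
  expect_equal(out$reason[8], "speed")

  # idempotence: re-filtering the output changes nothing
  again <- speed_filter(out)
  expect_identical(out$retained, again$retained)

  # post-condition: all consecutive retained speeds <= vmax
  kept <- out[out$retained, ]
  sp <- great_circle_distance(head(kept$lat, -1), head(kept$lon, -1),
                              tail(kept$lat, -1), tail(kept$lon, -1)) /
    as.numeric(diff(kept$time), units = "hours")
  expect_true(all(sp <= 8 + 1e-9))
})

test_that("class 3 fixes and track endpoints are immune to removal", {
  tr <- make_toy_track(n = 12, speed_kmh = 2, spike_at = 5, quality = "3")
  out <- speed_filter(as_argos_fixes(tr))
  # the spike is class 3, so it cannot be removed; neighbours are also
  # class 3; the filter must stop without emptying the track
  expect_true(out$retained[5])
  tr2 <- make_toy_track(n = 10, speed_kmh = 2, spike_at = c(1, 10))
  out2 <- speed_filter(as_argos_fixes(tr2))
  expect_true(out2$retained[1] && out2$retained[10])
})

test_that("speed filter matches the brute-force greedy oracle on random tracks", {
  set.seed(8)
  for (k in 1:30) {
    n <- sample(5:50, 1)
    spikes <- sample(2:(n - 1), sample(0:3, 1))
    qual <- sample(c("3", "2", "1", "0", "A", "B"), n, replace = TRUE)
    tr <- make_toy_track(n = n, speed_kmh = runif(1, 1, 5),
                         spike_at = spikes,
                         spike_km = runif(1, 15, 60))
    tr$quality <- qual
    fx <- as_argos_fixes(tr)
    out <- speed_filter(fx, vmax = 8)
    expect_equal(out$retained, oracle_speed_filter(fx, vmax = 8))
    # output is a subsequence of the input
    expect_true(all(which(!out$retained) %in% seq_len(n)))
  }
})

test_that("manual rejection list is honored", {
  tr <- make_toy_track(n = 6)
  rej <- data.frame(animal_id = "a1", time = tr$time[3])
  out <- speed_filter(as_argos_fixes(tr), manual_reject = rej)
  expect_false(out$retained[3])
  expect_equal(out$reason[3], "manual")
})
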