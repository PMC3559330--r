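colony <- c(lat = -64.76667, lon = -64.06667)

# Fixes at stated distances from the colony along a fixed bearing.
fixes_at_distances <- function(d_km, animal = "a1") {
  p <- destination_point(colony["lat"], colony["lon"], 60, d_km)
  data.frame(animal_id = animal,
             time = as.POSIXct("2011-01-10", tz = "UTC") +
               seq_along(d_km) * 1800,
             lat = p$lat, lon = p$lon, stringsAsFactors = FALSE)
}

test_that("trip segmentation splits runs at colony returns", {
  d <- c(0.1, 2, 6, 3, 0.2, 4, 7, 0.3)
  tr <- segment_trips(fixes_at_distances(d), colony["lat"], colony["lon"])
  expect_equal(length(unique(tr$trip_id)), 2)
  expect_equal(split(round(tr$dhi_km, 6), tr$trip_id),
               list(trip001 = c(2, 6, 3), trip002 = c(4, 7)),
               ignore_attr = TRUE)
  expect_false(any(tr$open))

  # all fixes at the colony: no trips
  none <- segment_trips(fixes_at_distances(c(0.1, 0.2, 0.3)),
                        colony["lat"], colony["lon"])
  expect_equal(nrow(none), 0)

  # single excursion with no return: one open trip
  open <- segment_trips(fixes_at_distances(c(0.1, 3, 5, 8)),
                        colony["lat"], colony["lon"])
  expect_equal(length(unique(open$trip_id)), 1)
  expect_true(all(open$open))
})

test_that("noiseless data give a degenerate exact mixed-model fit", {
  d <- toy_trip_fixture()
  d$dhi_km <- ifelse(d$regime == "diurnal", 5.4, 9.1)
  fit <- fit_lmm(d, "eq1", "identity")
  expect_true(fit$degenerate)
  expect_equal(unname(fit$beta), c(5.4, 9.1 - 5.4), tolerance = 1e-12)
  expect_equal(fit$sigma_b, 0)
  expect_equal(fit$sigma_e, 0)
})

test_that("ML log-likelihood matches a direct numerical oracle on the printed fixture", {
  d <- toy_trip_fixture()
  fit1 <- fit_lmm(d, "eq1", "identity")
  X1 <- model.matrix(~ factor(regime, c("diurnal", "semidiurnal")), d)
  ll1 <- oracle_lmm_loglik(d$dhi_km, X1, d$trip_id)
  expect_equal(fit1$loglik, ll1, tolerance = 1e-6)
  expect_equal(fit1$aic, 2 * 4 - 2 * fit1$loglik, tolerance = 1e-9)

  fit2 <- fit_lmm(d, "eq2", "identity")
  X2 <- model.matrix(~ factor(regime, c("diurnal", "semidiurnal")) +
                       amplitude_m + julian_day, d)
  ll2 <- oracle_lmm_loglik(d$dhi_km, X2, d$trip_id)
  expect_equal(fit2$loglik, ll2, tolerance = 1e-6)

  # log10 transform drops non-positive distances with a warning
  d2 <- d
  d2$dhi_km[1] <- 0
  expect_warning(f <- fit_lmm(d2, "eq1", "log10"), "non-positive")
  expect_equal(f$n_obs, nrow(d) - 1)
})

test_that("mixed-model fitting validates its design", {
  d <- toy_trip_fixture()
  expect_error(fit_lmm(d[d$regime == "diurnal", ], "eq1"), "both regimes")
  expect_error(fit_lmm(d[d$trip_id == "trip001", ], "eq1"), "2 trips")
})

test_that("parameter recovery: regime effect estimated without bias", {
  ests <- vapply(1:40, function(k) {
    d <- sim_trip_data(30, beta_d = 5.4, beta_s = 9.1, sigma_b = 1.4,
                       sigma_e = 2, seed = 500 + k)
    unname(fit_lmm(d, "eq1")$beta[2])
  }, numeric(1))
  expect_lt(abs(mean(ests) - 3.7), 0.35)
})

test_that("model comparison behaves like a likelihood-ratio test", {
  d <- toy_trip_fixture()
  fit1 <- fit_lmm(d, "eq1")
  fit2 <- fit_lmm(d, "eq2")
  cmp <- compare_models(fit1, fit2)
  expect_equal(cmp$df, 2)
  expect_equal(cmp$chi2, 2 * (fit2$loglik - fit1$loglik), tolerance = 1e-9)
  expect_equal(cmp$p, pchisq(cmp$chi2, 2, lower.tail = FALSE))
  expect_equal(cmp$delta_aic, fit2$aic - fit1$aic, tolerance = 1e-9)
  # argument order does not matter
  cmp_r <- compare_models(fit2, fit1)
  expect_equal(cmp_r$chi2, cmp$chi2)

  # identical models: chi2 = 0, p = 1
  same <- compare_models(fit1, fit1)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)

  # different data refused
  fit_other <- fit_lmm(d[-1, ], "eq2")
  expect_error(compare_models(fit1, fit_other), "same data")
})

test_that("residual normality check distinguishes gaussian from skewed residuals", {
  set.seed(18)
  p_norm <- vapply(1:10, function(k)
    check_residual_normality(rnorm(200))$p, numeric(1))
  expect_gte(sum(p_norm > 0.05), 9)
  p_skew <- vapply(1:10, function(k)
    check_residual_normality(rexp(600)^2)$p, numeric(1))
  expect_true(all(p_skew < 0.05))
  # beyond the Shapiro-Wilk limit the Anderson-Darling test takes over
  big <- check_residual_normality(rnorm(6000))
  expect_equal(big$method, "anderson-darling")
  expect_error(check_residual_normality(rep(1, 50)), "constant")
  expect_error(check_residual_normality(rnorm(5)), "at least 8")
})

test_that("kernel density surface integrates to one and tracks its sample", {
  # single point: mode at that point, integral ~ 1
  one <- data.frame(lat = -64.72, lon = -64.0)
  surf <- kde_surface(one, colony["lat"], colony["lon"], cell = 200,
                      bandwidth_m = 500)
  expect_equal(surf$integral, 1, tolerance = 0.01)
  peak <- which(surf$z == max(surf$z), arr.ind = TRUE)
  expect_lt(abs(surf$x[peak[1]] - surf$points[1, "x"]), 200)
  expect_lt(abs(surf$y[peak[2]] - surf$points[1, "y"]), 200)

  # two distant points: two equal modes
  two <- data.frame(lat = c(-64.72, -64.60), lon = c(-64.3, -63.9))
  s2 <- kde_surface(two, colony["lat"], colony["lon"], cell = 200,
                    bandwidth_m = 400)
  zmax <- sort(s2$z, decreasing = TRUE)
  expect_equal(zmax[1], zmax[2], tolerance = 0.02)
  expect_error(kde_surface(one[0, ], colony["lat"], colony["lon"]),
               "at least one")
})

test_that("kernel density agrees with an independent KDE implementation", {
  skip_if_not_installed("MASS")
  set.seed(19)
  pts <- data.frame(x = rnorm(400, 0, 2000), y = rnorm(400, 0, 1500))
  ll <- unproject_aeqd(pts$x, pts$y, colony["lat"], colony["lon"])
  h <- 800
  surf <- kde_surface(ll, colony["lat"], colony["lon"], cell = 250,
                      bandwidth_m = h)
  # MASS::kde2d parameterizes bandwidth as 4 * sd on the same grid
  ref <- MASS::kde2d(surf$points[, "x"], surf$points[, "y"],
                     h = 4 * h, n = c(length(surf$x), length(surf$y)),
                     lims = c(range(surf$x), range(surf$y)))
  expect_equal(surf$z, ref$z, tolerance = 1e-6)
})

test_that("95% contour area matches the smoothed-Gaussian closed form", {
  set.seed(20)
  sigma <- 2000; h <- 1500
  pts <- data.frame(x = rnorm(5000, 0, sigma), y = rnorm(5000, 0, sigma))
  ll <- unproject_aeqd(pts$x, pts$y, colony["lat"], colony["lon"])
  surf <- kde_surface(ll, colony["lat"], colony["lon"], cell = 725,
                      bandwidth_m = h)
  area <- contour_area_95(surf)
  want <- pi * (sigma^2 + h^2) * qchisq(0.95, 2) / 1e6
  expect_lt(abs(area - want) / want, 0.15)

  # scale equivariance: doubling coordinates and bandwidth quadruples area
  ll2 <- unproject_aeqd(2 * pts$x, 2 * pts$y, colony["lat"], colony["lon"])
  surf2 <- kde_surface(ll2, colony["lat"], colony["lon"], cell = 1450,
                       bandwidth_m = 2 * h)
  area2 <- contour_area_95(surf2)
  expect_equal(area2 / area, 4, tolerance = 0.05)

  # tight cluster much smaller than the bandwidth: single-kernel 95% disk
  tight <- data.frame(x = rnorm(500, 0, 10), y = rnorm(500, 0, 10))
  ll3 <- unproject_aeqd(tight$x, tight$y, colony["lat"], colony["lon"])
  surf3 <- kde_surface(ll3, colony["lat"], colony["lon"], cell = 100,
                       bandwidth_m = 1000)
  area3 <- contour_area_95(surf3)
  want3 <- pi * 1000^2 * qchisq(0.95, 2) / 1e6
  expect_lt(abs(area3 - want3) / want3, 0.15)
})

test_that("observation-percentile contours contain 95% of the sample", {
  set.seed(22)
  pts <- data.frame(x = rnorm(2000, 0, 2000), y = rnorm(2000, 0, 2000))
  ll <- unproject_aeqd(pts$x, pts$y, colony["lat"], colony["lon"])
  surf <- kde_surface(ll, colony["lat"], colony["lon"], cell = 500,
                      bandwidth_m = 1000)
  area_obs <- contour_area_95(surf, method = "observations")
  # for a Gaussian sample this rule converges on the sample 95% ellipse,
  # without bandwidth inflation
  want <- pi * 2000^2 * qchisq(0.95, 2) / 1e6
  expect_lt(abs(area_obs - want) / want, 0.15)
  expect_warning(
    contour_area_95(kde_surface(ll[1:10, ], colony["lat"], colony["lon"],
                                cell = 500, bandwidth_m = 1000),
                    method = "observations"),
    "unstable")
})
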