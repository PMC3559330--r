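# Foraging-location statistics: trip segmentation, random-intercept mixed
# models of distance-to-colony, and model comparison.

#' Segment fixes into foraging trips
#'
#' A trip is a maximal run of fixes farther than `radius` from the colony,
#' bounded by returns to within `radius`; the colony-proximal boundary fixes
#' are excluded from trips. Leading/trailing runs without a bounding return
#' still form trips, flagged `open`.
#'
#' @param fixes data.frame with `animal_id`, `time`, `lat`, `lon`, sorted in
#'   time per animal (rows with `retained == FALSE` are dropped first if the
#'   column is present). A `diving` column, if present, is carried through.
#' @param colony_lat,colony_lon colony coordinates, decimal degrees.
#' @param radius colony-return radius, km (default 0.5).
#' @return data.frame of class `trip_table`: `animal_id`, `trip_id`, `time`,
#'   `lat`, `lon`, `dhi_km` (distance to colony), `open`, plus `diving` when
#'   available. Zero qualifying fixes give zero rows.
#' @export
segment_trips <- function(fixes, colony_lat, colony_lon, radius = 0.5) {
  if (radius <= 0) stop("radius must be > 0")
  if (!is.null(fixes$retained)) fixes <- fixes[fixes$retained, , drop = FALSE]
  fixes <- fixes[order(fixes$animal_id, fixes$time), , drop = FALSE]
  out <- list()
  trip_counter <- 0L
  for (id in unique(fixes$animal_id)) {
    f <- fixes[fixes$animal_id == id, , drop = FALSE]
    d <- great_circle_distance(f$lat, f$lon, colony_lat, colony_lon)
    away <- d > radius
    if (!any(away)) next
    r <- rle(away)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      trip_counter <- trip_counter + 1L
      idx <- starts[k]:ends[k]
      open <- (starts[k] == 1) || (ends[k] == nrow(f))
      seg <- data.frame(animal_id = id,
                        trip_id = sprintf("trip%03d", trip_counter),
                        time = f$time[idx], lat = f$lat[idx],
                        lon = f$lon[idx], dhi_km = d[idx], open = open,
                        stringsAsFactors = FALSE)
      if (!is.null(f$diving)) seg$diving <- f$diving[idx]
      out[[length(out) + 1]] <- seg
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(animal_id = character(), trip_id = character(),
               time = as.POSIXct(character(), tz = "UTC"), lat = numeric(),
               lon = numeric(), dhi_km = numeric(), open = logical(),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("trip_table", "data.frame")
  res
}

#' Attach model covariates to a trip table
#'
#' Adds the day's tidal regime and amplitude (via [assign_regime()]), the
#' Julian day (day-of-year of the fix in station-local time) and log10 of
#' the distance.
#'
#' @param trips a `trip_table`.
#' @param calendar regime calendar.
#' @param day_offset hours, as in [assign_regime()].
#' @return the trip table with `regime`, `amplitude_m`, `julian_day`,
#'   `log10_dhi` columns.
#' @export
label_trip_covariates <- function(trips, calendar, day_offset = -3) {
  lab <- assign_regime(trips$time, calendar, day_offset)
  trips$regime <- lab$regime
  trips$amplitude_m <- lab$amplitude_m
  loc <- trips$time + day_offset * 3600
  trips$julian_day <- as.POSIXlt(loc, tz = "UTC")$yday + 1
  trips$log10_dhi <- ifelse(trips$dhi_km > 0, log10(trips$dhi_km), NA_real_)
  trips
}

#' Fit the random-intercept foraging-distance model
#'
#' Gaussian linear mixed model of distance-to-colony with a random intercept
#' per trip, fit by maximum likelihood (not REML, so AIC values are
#' comparable across fixed-effect structures). The `"eq1"` formula has tidal
#' regime as the only fixed effect; `"eq2"` adds daily tidal amplitude and
#' Julian day. Wald t statistics use a normal approximation for p-values.
#' AIC counts the fixed effects plus the two variance parameters.
#'
#' If the response is fit perfectly by the fixed effects (a noiseless
#' simulation), the model is degenerate: coefficients come from ordinary
#' least squares, both variances are zero, and the log-likelihood is
#' unbounded (`Inf`).
#'
#' @param data a labeled trip table (needs `dhi_km`, `regime`, `trip_id`;
#'   `"eq2"` also needs `amplitude_m`, `julian_day`). Rows with regime
#'   `"unclassified"` are dropped.
#' @param formula `"eq1"` or `"eq2"`.
#' @param transform `"identity"` or `"log10"` (non-positive distances are
#'   dropped with a warning).
#' @return object of class `lmm_result`: `beta`, `se`, `t`, `p` (named by
#'   coefficient), `sigma_b` (trip random-intercept SD), `sigma_e` (residual
#'   SD), `loglik`, `aic`, `n_obs`, `n_groups`, `transform`, `formula`,
#'   `residuals`.
#' @export
fit_lmm <- function(data, formula = c("eq1", "eq2"),
                    transform = c("identity", "log10")) {
  formula <- match.arg(formula)
  transform <- match.arg(transform)
  d <- as.data.frame(data)
  d <- d[d$regime %in% c("diurnal", "semidiurnal"), , drop = FALSE]
  if (transform == "log10") {
    bad <- !(d$dhi_km > 0)
    if (any(bad)) {
      warning(sum(bad), " non-positive distance(s) dropped under log10")
      d <- d[!bad, , drop = FALSE]
    }
    d$.resp <- log10(d$dhi_km)
  } else {
    d$.resp <- d$dhi_km
  }
  if (length(unique(d$trip_id)) < 2) stop("need at least 2 trips")
  if (length(unique(d$regime)) < 2)
    stop("both regimes must be present (singular design)")
  d$regime <- factor(d$regime, levels = c("diurnal", "semidiurnal"))
  rhs <- if (formula == "eq1") ".resp ~ regime" else
    ".resp ~ regime + amplitude_m + julian_day"
  fml <- as.formula(rhs)

  ls_fit <- lm(fml, data = d)
  if (sigma(ls_fit) < 1e-10) {
    beta <- coef(ls_fit)
    k <- length(beta) + 2
    res <- structure(list(
      beta = beta, se = rep(0, length(beta)), t = rep(Inf, length(beta)),
      p = rep(0, length(beta)), sigma_b = 0, sigma_e = 0,
      loglik = Inf, aic = -Inf, n_obs = nrow(d),
      n_groups = length(unique(d$trip_id)),
      transform = transform, formula = formula, degenerate = TRUE,
      residuals = residuals(ls_fit), k = k), class = "lmm_result")
    return(res)
  }

  mfml <- as.formula(paste(rhs, "+ (1 | trip_id)"))
  fit <- lme4::lmer(mfml, data = d, REML = FALSE)
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  tval <- beta / se
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma_b <- vc$sdcor[vc$grp == "trip_id"]
  sigma_e <- sigma(fit)
  ll <- as.numeric(logLik(fit))
  k <- length(beta) + 2
  structure(list(
    beta = beta, se = se, t = tval, p = 2 * pnorm(-abs(tval)),
    sigma_b = sigma_b, sigma_e = sigma_e, loglik = ll,
    aic = 2 * k - 2 * ll, n_obs = nrow(d),
    n_groups = length(unique(d$trip_id)),
    transform = transform, formula = formula, degenerate = FALSE,
    residuals = residuals(fit), k = k, fit = fit), class = "lmm_result")
}

#' @export
#' @method print lmm_result
print.lmm_result <- function(x, ...) {
  cat(sprintf("Random-intercept LMM (%s, %s response), ML fit\n",
              x$formula, x$transform))
  tab <- data.frame(estimate = x$beta, se = x$se, t = x$t, p = x$p)
  print(round(tab, 4))
  cat(sprintf("  sigma_trip = %.3f  sigma_resid = %.3f\n",
              x$sigma_b, x$sigma_e))
  cat(sprintf("  logLik = %.2f  AIC = %.1f  (n = %d obs, %d trips)\n",
              x$loglik, x$aic, x$n_obs, x$n_groups))
  invisible(x)
}

#' Likelihood-ratio / AIC comparison of nested mixed models
#'
#' Both fits must be maximum-likelihood fits to the same data and transform,
#' with nested fixed-effect sets. The statistic is
#' `chi2 = 2 * (logLik_big - logLik_small)` on df = difference in number of
#' fixed effects; `delta_aic = AIC(big) - AIC(small)` (positive favours the
#' smaller model).
#'
#' @param fit_a,fit_b `lmm_result` objects (either order).
#' @return list (`chi2`, `df`, `p`, `delta_aic`, `aic_small`, `aic_big`).
#' @export
compare_models <- function(fit_a, fit_b) {
  small <- if (length(fit_a$beta) <= length(fit_b$beta)) fit_a else fit_b
  big <- if (length(fit_a$beta) <= length(fit_b$beta)) fit_b else fit_a
  if (small$n_obs != big$n_obs || small$transform != big$transform)
    stop("fits are not on the same data and transform")
  if (!all(names(small$beta) %in% names(big$beta)))
    stop("fixed-effect sets are not nested")
  df <- length(big$beta) - length(small$beta)
  chi2 <- max(0, 2 * (big$loglik - small$loglik))
  p <- if (df == 0) 1 else pchisq(chi2, df = df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p = p,
       delta_aic = big$aic - small$aic,
       aic_small = small$aic, aic_big = big$aic)
}

#' Normality check of model residuals
#'
#' Shapiro-Wilk test of the within-group residuals; for samples beyond the
#' Shapiro-Wilk implementation limit (n > 5000) the Anderson-Darling test is
#' used instead (noted in the result).
#'
#' @param residuals numeric residual vector (n >= 8), or an `lmm_result`.
#' @return list (`stat`, `p`, `method`).
#' @export
check_residual_normality <- function(residuals) {
  if (inherits(residuals, "lmm_result")) residuals <- residuals$residuals
  r <- residuals[is.finite(residuals)]
  if (length(r) < 8) stop("need at least 8 residuals")
  if (sd(r) == 0) stop("constant residuals: normality test degenerate")
  if (length(r) <= 5000) {
    ht <- shapiro.test(r)
    list(stat = unname(ht$statistic), p = ht$p.value,
         method = "shapiro-wilk")
  } else {
    ht <- nortest::ad.test(r)
    list(stat = unname(ht$statistic), p = ht$p.value,
         method = "anderson-darling")
  }
}
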