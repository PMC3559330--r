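# Circular statistics: the Mardia-Watson-Wheeler uniform-scores two-sample
# test and a Watson U^2 goodness-of-fit test against a fitted von Mises
# distribution.

#' Mardia-Watson-Wheeler uniform-scores test
#'
#' Nonparametric two-sample test for a common circular distribution. The
#' pooled angles are circularly ranked and mapped to uniform scores
#' `gamma_k = 2*pi*rank_k / N` (tied angles receive averaged ranks); with
#' per-sample resultants `C_i = sum cos(gamma)`, `S_i = sum sin(gamma)`, the
#' statistic is `W = 2 * sum_i (C_i^2 + S_i^2) / n_i`. Under the null W is
#' asymptotically chi-squared with 2 df. The permutation p-value resamples
#' group labels; when all label assignments number at most `n_perm` they are
#' enumerated exhaustively, otherwise `n_perm` random assignments are drawn
#' and the add-one estimator is used.
#'
#' @param angles_a,angles_b samples of angles, degrees (each length >= 2).
#' @param method "asymptotic" (default) or "permutation" (reports both).
#' @param n_perm permutation budget.
#' @param seed optional integer seed for the permutation draw.
#' @return object of class `mww_result`: `W`, `p_asymptotic`,
#'   `p_permutation` (or NA), `n1`, `n2`.
#' @export
mww_test <- function(angles_a, angles_b,
                     method = c("asymptotic", "permutation"),
                     n_perm = 9999, seed = NULL) {
  method <- match.arg(method)
  n1 <- length(angles_a); n2 <- length(angles_b)
  if (n1 < 2 || n2 < 2) stop("each sample needs at least 2 angles")
  a <- angles_a %% 360; b <- angles_b %% 360
  all_ang <- c(a, b)
  N <- n1 + n2
  if (diff(range(all_ang)) < 1e-12) {
    warning("all angles identical; test degenerate")
    return(structure(list(W = 0, p_asymptotic = 1, p_permutation = NA_real_,
                          n1 = n1, n2 = n2), class = "mww_result"))
  }
  gamma <- 2 * pi * rank(all_ang, ties.method = "average") / N
  cg <- cos(gamma); sg <- sin(gamma)
  w_stat <- function(in_a) {
    c1 <- sum(cg[in_a]); s1 <- sum(sg[in_a])
    c2 <- sum(cg) - c1; s2 <- sum(sg) - s1
    2 * ((c1^2 + s1^2) / n1 + (c2^2 + s2^2) / n2)
  }
  in_a <- c(rep(TRUE, n1), rep(FALSE, n2))
  W <- w_stat(in_a)
  p_asym <- pchisq(W, df = 2, lower.tail = FALSE)
  p_perm <- NA_real_
  if (method == "permutation") {
    n_comb <- choose(N, n1)
    if (n_comb <= n_perm) {
      combs <- utils::combn(N, n1)
      wp <- apply(combs, 2, function(ix) {
        m <- rep(FALSE, N); m[ix] <- TRUE; w_stat(m)
      })
      p_perm <- mean(wp >= W - 1e-12)
    } else {
      if (!is.null(seed)) set.seed(seed)
      wp <- replicate(n_perm, {
        m <- rep(FALSE, N); m[sample.int(N, n1)] <- TRUE; w_stat(m)
      })
      p_perm <- (1 + sum(wp >= W - 1e-12)) / (1 + n_perm)
    }
  }
  structure(list(W = W, p_asymptotic = p_asym, p_permutation = p_perm,
                 n1 = n1, n2 = n2), class = "mww_result")
}

#' @export
#' @method print mww_result
print.mww_result <- function(x, ...) {
  cat("Mardia-Watson-Wheeler uniform-scores test\n")
  cat(sprintf("  W = %.4f  (n1 = %d, n2 = %d)\n", x$W, x$n1, x$n2))
  cat(sprintf("  p (chi-squared, 2 df) = %.4g\n", x$p_asymptotic))
  if (!is.na(x$p_permutation))
    cat(sprintf("  p (permutation)       = %.4g\n", x$p_permutation))
  invisible(x)
}

# Ratio of modified Bessel functions I1/I0, computed on the scaled Bessel
# functions so large kappa does not overflow.
.bessel_ratio_A1 <- function(kappa) {
  besselI(kappa, 1, expon.scaled = TRUE) /
    besselI(kappa, 0, expon.scaled = TRUE)
}

#' Fit a von Mises distribution by maximum likelihood
#'
#' The mean direction is the direction of the sample resultant; the
#' concentration kappa solves `A1(kappa) = Rbar` (mean resultant length),
#' inverted by Newton iteration from the standard small/large-R series
#' starting values, to tolerance 1e-10.
#'
#' @param angles_deg angles, degrees.
#' @return list (`mu_deg`, `kappa`, `rbar`, `n`).
#' @export
fit_vonmises <- function(angles_deg) {
  th <- angles_deg * pi / 180
  n <- length(th)
  cbar <- mean(cos(th)); sbar <- mean(sin(th))
  rbar <- sqrt(cbar^2 + sbar^2)
  mu <- atan2(sbar, cbar)
  if (rbar < 1e-8)
    return(list(mu_deg = (mu * 180 / pi) %% 360, kappa = 0, rbar = rbar,
                n = n))
  rbar_c <- min(rbar, 1 - 1e-12)
  k <- if (rbar_c < 0.53) {
    2 * rbar_c + rbar_c^3 + 5 * rbar_c^5 / 6
  } else if (rbar_c < 0.85) {
    -0.4 + 1.39 * rbar_c + 0.43 / (1 - rbar_c)
  } else {
    1 / (rbar_c^3 - 4 * rbar_c^2 + 3 * rbar_c)
  }
  for (it in 1:100) {
    a1 <- .bessel_ratio_A1(k)
    f <- a1 - rbar_c
    fp <- 1 - a1 / k - a1^2
    step <- f / fp
    k_new <- k - step
    if (k_new <= 0) k_new <- k / 2
    if (abs(k_new - k) < 1e-10 * max(1, k)) { k <- k_new; break }
    k <- k_new
  }
  list(mu_deg = (mu * 180 / pi) %% 360, kappa = min(k, 1e5), rbar = rbar,
       n = n)
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler; uniform on the circle when kappa ~ 0.
#'
#' @param n sample size.
#' @param mu_deg mean direction, degrees.
#' @param kappa concentration (>= 0).
#' @return angles in degrees, in \[0, 360).
#' @export
rvonmises <- function(n, mu_deg, kappa) {
  if (kappa < 1e-8) return(runif(n, 0, 360))
  mu <- mu_deg * pi / 180
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u1 <- runif(1); u2 <- runif(1); u3 <- runif(1)
      z <- cos(pi * u1)
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
        out[i] <- sign(u3 - 0.5) * acos(f) + mu
        break
      }
    }
  }
  (out * 180 / pi) %% 360
}

# CDF of the von Mises distribution measured from the mean direction:
# F(z) for z in [0, 2*pi), by trapezoidal integration on a fine grid.
.pvonmises_centered <- function(z, kappa, ngrid = 4096) {
  grid <- seq(0, 2 * pi, length.out = ngrid + 1)
  dens <- exp(kappa * (cos(grid) - 1))  # scaled; normalized below
  cdf <- c(0, cumsum((dens[-1] + dens[-(ngrid + 1)]) / 2)) *
    (2 * pi / ngrid)
  cdf <- cdf / cdf[ngrid + 1]
  approx(grid, cdf, xout = z, rule = 2)$y
}

#' Watson U-squared test against a fitted von Mises distribution
#'
#' Fits a von Mises by maximum likelihood, computes the Watson U^2 statistic
#' of the probability-integral-transformed sample, and calibrates its
#' p-value by parametric bootstrap (refitting on each bootstrap sample, so
#' the estimation step is accounted for).
#'
#' @param angles_deg angles, degrees (n >= 10).
#' @param n_boot bootstrap replicates.
#' @param seed optional integer seed.
#' @return list (`u2`, `p`, `mu_deg`, `kappa`, `n_boot`).
#' @export
vonmises_gof <- function(angles_deg, n_boot = 199, seed = NULL) {
  n <- length(angles_deg)
  if (n < 10) stop("need at least 10 angles")
  if (!is.null(seed)) set.seed(seed)
  u2_of <- function(ang, fit) {
    z <- ((ang - fit$mu_deg) * pi / 180) %% (2 * pi)
    u <- sort(.pvonmises_centered(z, fit$kappa))
    i <- seq_len(n)
    sum((u - (2 * i - 1) / (2 * n))^2) + 1 / (12 * n) -
      n * (mean(u) - 0.5)^2
  }
  fit <- fit_vonmises(angles_deg)
  u2 <- u2_of(angles_deg, fit)
  boots <- replicate(n_boot, {
    x <- rvonmises(n, fit$mu_deg, fit$kappa)
    u2_of(x, fit_vonmises(x))
  })
  p <- (1 + sum(boots >= u2)) / (1 + n_boot)
  list(u2 = u2, p = p, mu_deg = fit$mu_deg, kappa = fit$kappa,
       n_boot = n_boot)
}
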