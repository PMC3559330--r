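# Independent brute-force oracles. These re-derive expected results by the
# most direct route available (explicit loops, full enumeration, direct
# likelihood maximisation) and are deliberately kept separate from the
# package implementations they check.

# Greedy maximum-speed filter, re-implemented with explicit per-iteration
# recomputation.
oracle_speed_filter <- function(fixes, vmax = 8) {
  f <- fixes[order(fixes$animal_id, fixes$time), ]
  keep <- if (is.null(f$retained)) rep(TRUE, nrow(f)) else f$retained
  for (id in unique(f$animal_id)) {
    all_rows <- which(f$animal_id == id)
    repeat {
      rows <- which(f$animal_id == id & keep)
      if (length(rows) < 2) break
      sp <- numeric(length(rows) - 1)
      for (k in seq_len(length(rows) - 1)) {
        i <- rows[k]; j <- rows[k + 1]
        dt <- as.numeric(difftime(f$time[j], f$time[i], units = "hours"))
        dd <- great_circle_distance(f$lat[i], f$lon[i], f$lat[j], f$lon[j])
        sp[k] <- if (dt <= 0) (if (dd > 0) Inf else 0) else dd / dt
      }
      viol <- which(sp > vmax)
      if (length(viol) == 0) break
      cand <- sort(unique(c(viol, viol + 1)))
      ok <- vapply(cand, function(k) {
        i <- rows[k]
        !(f$quality[i] == "3" || i == all_rows[1] ||
            i == all_rows[length(all_rows)])
      }, logical(1))
      cand <- cand[ok]
      if (length(cand) == 0) break
      imp <- matrix(NA_real_, 2, length(cand))
      for (ci in seq_along(cand)) {
        k <- cand[ci]
        s <- c(-Inf, -Inf)
        if (k > 1) s[1] <- sp[k - 1]
        if (k <= length(sp)) s[2] <- sp[k]
        imp[, ci] <- c(max(s), min(s))
      }
      best <- cand[imp[1, ] == max(imp[1, ])]
      if (length(best) > 1) {
        mins <- imp[2, match(best, cand)]
        best <- best[mins == max(mins)]
      }
      kdrop <- max(best)
      keep[rows[kdrop]] <- FALSE
    }
  }
  keep[order(order(fixes$animal_id, fixes$time))]
}

# Brute-force high-tide count per (offset-shifted) day: strict local maxima,
# prominence by full left/right scans, separation by repeated selection of
# the highest remaining peak.
oracle_daily_high_count <- function(series, dates, day_offset = -3,
                                    min_sep = 8, min_prom = 0.1) {
  x <- series$height_m; tt <- series$time; n <- length(x)
  peaks <- integer(0)
  for (i in 2:(n - 1)) {
    if (x[i] > x[i - 1] && x[i] >= x[i + 1]) peaks <- c(peaks, i)
  }
  keep <- logical(length(peaks))
  for (k in seq_along(peaks)) {
    i <- peaks[k]
    hl <- which(x[seq_len(i - 1)] > x[i])
    lb <- if (length(hl)) min(x[max(hl):i]) else min(x[1:i])
    hr <- which(x[(i + 1):n] > x[i])
    rb <- if (length(hr)) min(x[i:(i + min(hr))]) else min(x[i:n])
    keep[k] <- (x[i] - max(lb, rb)) >= min_prom
  }
  peaks <- peaks[keep]
  sel <- integer(0)
  remaining <- peaks
  while (length(remaining) > 0) {
    top <- remaining[x[remaining] == max(x[remaining])]
    i <- min(top)
    sel <- c(sel, i)
    gap_h <- abs(as.numeric(tt[remaining]) - as.numeric(tt[i])) / 3600
    remaining <- remaining[gap_h >= min_sep & remaining != i]
  }
  d <- as.Date(tt[sel] + day_offset * 3600, tz = "UTC")
  vapply(dates, function(day) sum(d == day), integer(1))
}

# Even-odd point-in-polygon by explicit edge-crossing count (boundary not
# distinguished; callers avoid boundary points).
oracle_point_in_polygon <- function(px, py, poly) {
  xs <- poly$lon; ys <- poly$lat
  n <- length(xs)
  if (xs[1] == xs[n] && ys[1] == ys[n]) n <- n - 1
  crossings <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    y1 <- ys[i]; y2 <- ys[j]; x1 <- xs[i]; x2 <- xs[j]
    if ((y1 <= py && y2 > py) || (y2 <= py && y1 > py)) {
      xc <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
      if (xc > px) crossings <- crossings + 1
    }
  }
  crossings %% 2 == 1
}

# All-pairs dive/fix merge labels.
oracle_merge_labels <- function(fix_times, events, window) {
  vapply(as.numeric(fix_times), function(t) {
    if (nrow(events) == 0) return(FALSE)
    for (k in seq_len(nrow(events))) {
      s <- as.numeric(events$start[k]); e <- as.numeric(events$end[k])
      gap <- if (t >= s && t <= e) 0 else min(abs(t - s), abs(t - e))
      if (gap <= window) return(TRUE)
    }
    FALSE
  }, logical(1))
}

# Direct ML log-likelihood of the Gaussian random-intercept model, by
# explicit multivariate-normal likelihood and numerical maximisation over
# (log sigma_b, log sigma_e) with GLS fixed effects.
oracle_lmm_loglik <- function(y, X, group) {
  n <- length(y)
  Z <- outer(group, unique(group), "==") * 1
  negll <- function(par) {
    sb2 <- exp(2 * par[1]); se2 <- exp(2 * par[2])
    V <- diag(se2, n) + sb2 * (Z %*% t(Z))
    Vi <- solve(V)
    XtVi <- t(X) %*% Vi
    beta <- solve(XtVi %*% X, XtVi %*% y)
    r <- y - X %*% beta
    ld <- determinant(V, logarithm = TRUE)$modulus
    0.5 * (n * log(2 * pi) + as.numeric(ld) +
             as.numeric(t(r) %*% Vi %*% r))
  }
  best <- Inf
  for (start in list(c(0, 0), c(log(0.5), log(0.5)), c(log(2), log(1)),
                     c(-3, 0))) {
    o <- optim(start, negll, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
    if (o$value < best) best <- o$value
  }
  -best
}

# Exhaustive Mardia-Watson-Wheeler permutation p-value: every assignment of
# n1 of the pooled angles to the first group, W computed from scratch.
oracle_mww_exhaustive_p <- function(angles_a, angles_b) {
  n1 <- length(angles_a); n2 <- length(angles_b)
  pooled <- c(angles_a, angles_b) %% 360
  N <- n1 + n2
  gamma <- 2 * pi * rank(pooled, ties.method = "average") / N
  w_of <- function(ix_a) {
    ca <- sum(cos(gamma[ix_a])); sa <- sum(sin(gamma[ix_a]))
    cb <- sum(cos(gamma[-ix_a])); sb <- sum(sin(gamma[-ix_a]))
    2 * ((ca^2 + sa^2) / n1 + (cb^2 + sb^2) / n2)
  }
  w_obs <- w_of(seq_len(n1))
  combs <- combn(N, n1)
  wp <- apply(combs, 2, w_of)
  mean(wp >= w_obs - 1e-12)
}
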