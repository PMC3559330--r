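# TDR processing: zero-offset correction of sensor drift, dive detection,
# and time-merging of dives with location fixes.

#' Zero-offset-correct a 1 Hz depth series
#'
#' Running-filter baseline: a centered running quantile (`q` over a window
#' of `w1` seconds) tracks the surface reading through dives, followed by a
#' morphological opening (running minimum then running maximum, both over
#' `w2` seconds) that removes the positive bias the quantile picks up
#' inside dives longer than `w1` while following monotone drift without
#' lag. The baseline is subtracted so surface segments read ~0 m. Defaults
#' (w1 = 120 s, w2 = 1800 s, q = 0.05) span surface intervals but not full
#' foraging bouts.
#'
#' @param series a `dive_series` (1 Hz `time`, `depth_m`).
#' @param w1 first-pass window, seconds.
#' @param w2 second-pass window, seconds.
#' @param q first-pass quantile.
#' @return corrected `dive_series` (attribute `corrected = TRUE`; any
#'   `dive_log` attribute is carried over).
#' @export
zero_offset_correct <- function(series, w1 = 120, w2 = 1800, q = 0.05) {
  n <- nrow(series)
  if (n < w1 + w2) stop("series shorter than the filter windows")
  step <- median(diff(as.numeric(series$time)))
  if (!isTRUE(all.equal(step, 1, tolerance = 0.1)))
    warning("series does not look like 1 Hz sampling")
  base1 <- run_quantile_center(series$depth_m, as.integer(w1), q)
  base2 <- run_max_center(run_min_center(base1, as.integer(w2)),
                          as.integer(w2))
  out <- data.frame(time = series$time, depth_m = series$depth_m - base2)
  class(out) <- c("dive_series", "data.frame")
  attr(out, "dive_log") <- attr(series, "dive_log")
  attr(out, "corrected") <- TRUE
  out
}

#' Detect foraging dives
#'
#' Maximal contiguous runs of samples strictly deeper than `threshold`
#' become dive events; an excursion to exactly the threshold is not a dive.
#' Start and end are the first and last samples beyond the threshold.
#'
#' @param series a corrected `dive_series`.
#' @param threshold foraging-dive depth threshold, metres (default 5).
#' @return data.frame (`start`, `end`, `max_depth`, `duration_s`).
#' @export
detect_dives <- function(series, threshold = 5) {
  if (!isTRUE(attr(series, "corrected")))
    warning("series is not zero-offset corrected")
  deep <- series$depth_m > threshold
  r <- rle(deep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  if (!any(keep)) {
    return(data.frame(start = series$time[integer(0)],
                      end = series$time[integer(0)],
                      max_depth = numeric(0), duration_s = numeric(0)))
  }
  s <- starts[keep]; e <- ends[keep]
  data.frame(
    start = series$time[s],
    end = series$time[e],
    max_depth = vapply(seq_along(s), function(i)
      max(series$depth_m[s[i]:e[i]]), numeric(1)),
    duration_s = as.numeric(series$time[e]) - as.numeric(series$time[s]) + 1
  )
}

#' Label location fixes as diving or non-diving
#'
#' A fix is a diving (foraging) location if its time is within `window`
#' seconds (inclusive) of a dive event, measured to the nearest point of the
#' dive interval: the gap is zero for a fix inside the interval.
#'
#' @param fixes data.frame with a `time` column.
#' @param events dive events ([detect_dives()]).
#' @param window merge window, seconds (default 150).
#' @return the fixes with logical column `diving` added.
#' @export
merge_dive_locations <- function(fixes, events, window = 150) {
  if (window < 0) stop("window must be >= 0")
  ft <- as.numeric(fixes$time)
  if (nrow(events) == 0) {
    fixes$diving <- rep(FALSE, length(ft))
    return(fixes)
  }
  s <- as.numeric(events$start)
  e <- as.numeric(events$end)
  fixes$diving <- vapply(ft, function(t) {
    gap <- pmax(0, pmax(s - t, t - e))
    min(gap) <= window
  }, logical(1))
  fixes
}
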