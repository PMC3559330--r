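#' Simulate a 1 Hz time-depth-recorder series for one trip
#'
#' Square-wave dives at known times are superimposed on a linear sensor
#' drift plus small Gaussian noise. The ground-truth dive log is attached as
#' attribute `"dive_log"` so downstream zero-offset correction and dive
#' detection can be scored against it.
#'
#' @param trip either a data.frame with a `time` column (the record spans
#'   its range) or a POSIXct vector of length 2 (start, end).
#' @param dive_depths depths of the dives, metres (positive down); one dive
#'   per element, evenly spaced through the record. Empty vector = no dives.
#' @param drift_rate sensor drift, metres per minute (>= 0 typical).
#' @param seed optional integer seed.
#' @param dive_duration_s duration of each square dive, seconds.
#' @param noise_sd depth noise SD, metres.
#' @param dive_starts optional POSIXct vector of dive start times (one per
#'   element of `dive_depths`); default: evenly spaced through the record.
#' @return data.frame of class `dive_series` with columns `time`, `depth_m`;
#'   attributes `dive_log` (start, end, max_depth) and `corrected = FALSE`.
#' @export
gen_dive_record <- function(trip, dive_depths, drift_rate = 0.01,
                            seed = NULL, dive_duration_s = 90,
                            noise_sd = 0.05, dive_starts = NULL) {
  if (is.data.frame(trip)) {
    t0 <- min(trip$time); t1 <- max(trip$time)
  } else {
    t0 <- trip[1]; t1 <- trip[2]
  }
  dur <- as.numeric(difftime(t1, t0, units = "secs"))
  if (dur <= 0) stop("trip duration must be positive")
  if (length(dive_depths) > 0 && any(dive_depths <= 0))
    stop("dive_depths must be positive")
  if (!is.null(seed)) set.seed(seed)

  secs <- 0:floor(dur)
  depth <- drift_rate * secs / 60
  if (noise_sd > 0) depth <- depth + rnorm(length(secs), 0, noise_sd)

  k <- length(dive_depths)
  log <- data.frame(start = as.POSIXct(character(), tz = "UTC"),
                    end = as.POSIXct(character(), tz = "UTC"),
                    max_depth = numeric())
  if (k > 0) {
    if (is.null(dive_starts)) {
      if (dur < k * (dive_duration_s + 120))
        stop("record too short for the requested dives")
      starts <- round(seq(60, dur - dive_duration_s - 60, length.out = k))
    } else {
      if (length(dive_starts) != k)
        stop("dive_starts must match dive_depths in length")
      starts <- round(as.numeric(dive_starts) - as.numeric(t0))
      starts <- pmin(pmax(starts, 0), dur - dive_duration_s)
      if (k > 1 && any(diff(sort(starts)) < dive_duration_s))
        stop("dives overlap")
      ord <- order(starts)
      starts <- starts[ord]
      dive_depths <- dive_depths[ord]
    }
    for (i in seq_len(k)) {
      idx <- secs >= starts[i] & secs < starts[i] + dive_duration_s
      depth[idx] <- depth[idx] + dive_depths[i]
    }
    log <- data.frame(start = t0 + starts,
                      end = t0 + starts + dive_duration_s - 1,
                      max_depth = dive_depths)
  }
  out <- data.frame(time = t0 + secs, depth_m = depth)
  class(out) <- c("dive_series", "data.frame")
  attr(out, "dive_log") <- log
  attr(out, "corrected") <- FALSE
  out
}
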