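# Tidal regime classification: detect high tides, label each day diurnal or
# semidiurnal by the number of high tides it contains, and compute the daily
# amplitude (half the daily range).

# Standard peak prominence: height above the higher of the two key saddles
# (minimum on the path to higher terrain on each side; series edge if no
# higher terrain).
.peak_prominence <- function(x, peaks) {
  vapply(peaks, function(i) {
    h <- x[i]
    lmin <- h
    j <- i
    while (j > 1) {
      j <- j - 1
      if (x[j] > h) break
      if (x[j] < lmin) lmin <- x[j]
    }
    rmin <- h
    j <- i
    n <- length(x)
    while (j < n) {
      j <- j + 1
      if (x[j] > h) break
      if (x[j] < rmin) rmin <- x[j]
    }
    h - max(lmin, rmin)
  }, numeric(1))
}

#' Detect high tides in a gauge record
#'
#' High tide is operationalized as a local maximum of the sea-level series
#' with prominence at least `min_prominence`, with successive highs at least
#' `min_separation` apart (the default 8 h separates semidiurnal highs,
#' ~12.4 h apart, without merging them). Where two candidate highs fall
#' closer than the separation, the higher one is kept. Series endpoints are
#' never returned as maxima.
#'
#' @param series a `tide_series` (regular `time`, `height_m`).
#' @param min_separation minimum spacing between reported highs, hours.
#' @param min_prominence minimum peak prominence, metres.
#' @return POSIXct vector of high-tide times, sorted.
#' @export
detect_high_tides <- function(series, min_separation = 8,
                              min_prominence = 0.1) {
  x <- series$height_m
  tt <- series$time
  n <- length(x)
  span_h <- as.numeric(difftime(tt[n], tt[1], units = "hours"))
  if (span_h < 2 * min_separation)
    stop("series shorter than twice the minimum separation")
  i <- 2:(n - 1)
  cand <- i[x[i] > x[i - 1] & x[i] >= x[i + 1]]
  if (length(cand) == 0) return(tt[integer(0)])
  prom <- .peak_prominence(x, cand)
  cand <- cand[prom >= min_prominence]
  if (length(cand) == 0) return(tt[integer(0)])
  # enforce separation, keeping higher peaks first
  ord <- cand[order(-x[cand], cand)]
  kept_t <- numeric(0)
  kept <- integer(0)
  for (i in ord) {
    ti <- as.numeric(tt[i])
    if (length(kept_t) == 0 ||
        min(abs(kept_t - ti)) >= min_separation * 3600) {
      kept <- c(kept, i)
      kept_t <- c(kept_t, ti)
    }
  }
  tt[sort(kept)]
}

#' Label calendar days as diurnal or semidiurnal
#'
#' A day (shifted into station-local time by `day_offset`) with exactly one
#' high tide is diurnal; a day with two or more is semidiurnal; a day with
#' none (gauge gap or detection dropout) is unclassified.
#'
#' @param high_tides sorted POSIXct high-tide times.
#' @param span Date vector: either the full sequence of days or its range.
#' @param day_offset hours added to UTC before taking the calendar date
#'   (station-local offset; default -3).
#' @return regime-calendar data.frame (`date`, `regime`, `n_high_tides`).
#' @export
classify_days <- function(high_tides, span, day_offset = -3) {
  days <- if (length(span) == 2) seq(span[1], span[2], by = "day") else span
  shifted <- as.Date(high_tides + day_offset * 3600, tz = "UTC")
  counts <- table(shifted)
  n <- as.integer(counts[as.character(days)])
  n[is.na(n)] <- 0L
  regime <- ifelse(n == 1, "diurnal",
                   ifelse(n >= 2, "semidiurnal", "unclassified"))
  data.frame(date = days, regime = regime, n_high_tides = n,
             stringsAsFactors = FALSE)
}

#' Daily tidal amplitude
#'
#' Amplitude of a day is half its sea-level range, (max - min) / 2, over the
#' samples falling in that (offset-shifted) day.
#'
#' @inheritParams classify_days
#' @param series a `tide_series`.
#' @param span optional Date vector (full sequence or range); default all
#'   days present in the record.
#' @return data.frame (`date`, `amplitude_m`); `NA` for empty days.
#' @export
daily_amplitude <- function(series, span = NULL, day_offset = -3) {
  d <- as.Date(series$time + day_offset * 3600, tz = "UTC")
  if (is.null(span)) {
    days <- sort(unique(d))
  } else {
    days <- if (length(span) == 2) seq(span[1], span[2], by = "day") else span
  }
  amp <- vapply(days, function(day) {
    h <- series$height_m[d == day]
    if (length(h) == 0) return(NA_real_)
    (max(h) - min(h)) / 2
  }, numeric(1))
  data.frame(date = days, amplitude_m = amp)
}

#' Build a regime calendar from a tide series
#'
#' Convenience wrapper: detects high tides, classifies days, and attaches
#' daily amplitudes. Only days with full gauge coverage (the modal number of
#' samples per day) are included, so edge days truncated by the day offset
#' do not produce spurious labels.
#'
#' @inheritParams detect_high_tides
#' @inheritParams classify_days
#' @return regime-calendar data.frame
#'   (`date`, `regime`, `n_high_tides`, `amplitude_m`).
#' @export
build_regime_calendar <- function(series, min_separation = 8,
                                  min_prominence = 0.1, day_offset = -3) {
  d <- as.Date(series$time + day_offset * 3600, tz = "UTC")
  per_day <- table(d)
  full <- as.Date(names(per_day)[per_day == max(per_day)])
  highs <- detect_high_tides(series, min_separation, min_prominence)
  cal <- classify_days(highs, full, day_offset)
  amp <- daily_amplitude(series, full, day_offset)
  cal$amplitude_m <- amp$amplitude_m[match(cal$date, amp$date)]
  class(cal) <- c("regime_calendar", "data.frame")
  cal
}

#' Assign a regime (and daily amplitude) to timestamps
#'
#' Each timestamp receives the regime and amplitude of its (offset-shifted)
#' calendar day; timestamps on days not covered by the calendar are labeled
#' unclassified.
#'
#' @param times POSIXct vector.
#' @param calendar regime calendar.
#' @param day_offset hours, as in [classify_days()].
#' @return data.frame (`regime`, `amplitude_m`) aligned with `times`.
#' @export
assign_regime <- function(times, calendar, day_offset = -3) {
  d <- as.Date(times + day_offset * 3600, tz = "UTC")
  i <- match(d, calendar$date)
  regime <- ifelse(is.na(i), "unclassified", calendar$regime[i])
  amp <- ifelse(is.na(i), NA_real_, calendar$amplitude_m[i])
  data.frame(regime = regime, amplitude_m = amp, stringsAsFactors = FALSE)
}
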