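# ARGOS track cleaning: land masking plus a sequential maximum-speed filter.

#' Coerce a table of ARGOS fixes
#'
#' Validates columns, coordinate ranges, quality classes and per-animal time
#' ordering, and adds `retained`/`reason` bookkeeping columns.
#'
#' @param d data.frame with `animal_id`, `time`, `lat`, `lon`, `quality`.
#' @return data.frame of class `argos_fixes`.
#' @export
as_argos_fixes <- function(d) {
  need <- c("animal_id", "time", "lat", "lon", "quality")
  if (!all(need %in% names(d)))
    stop("fixes need columns: ", paste(need, collapse = ", "))
  .check_coords(d$lat, d$lon)
  if (!all(d$quality %in% .argos_classes))
    stop("quality must be one of 3,2,1,0,A,B")
  ord <- order(d$animal_id, d$time)
  d <- d[ord, , drop = FALSE]
  if (is.null(d$retained)) d$retained <- TRUE
  if (is.null(d$reason)) d$reason <- NA_character_
  rownames(d) <- NULL
  class(d) <- c("argos_fixes", "data.frame")
  d
}

# Point-in-polygon, even-odd rule. Returns 0 outside, 1 on the boundary,
# 2 strictly inside. poly is a data.frame lon/lat (closed or open ring).
.point_in_polygon <- function(px, py, poly, eps = 1e-12) {
  xs <- poly$lon; ys <- poly$lat
  n <- length(xs)
  if (xs[1] == xs[n] && ys[1] == ys[n]) n <- n - 1
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- xs[i]; yi <- ys[i]; xj <- xs[j]; yj <- ys[j]
    # boundary: collinear and within the segment's bounding box
    cr <- (xj - xi) * (py - yi) - (yj - yi) * (px - xi)
    if (abs(cr) < eps &&
        px >= min(xi, xj) - eps && px <= max(xi, xj) + eps &&
        py >= min(yi, yj) - eps && py <= max(yi, yj) + eps) {
      return(1L)
    }
    if ((yi > py) != (yj > py)) {
      xint <- xi + (py - yi) / (yj - yi) * (xj - xi)
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  if (inside) 2L else 0L
}

#' Reject fixes on land
#'
#' Marks fixes strictly inside any land polygon as rejected
#' (`reason = "land"`). Points exactly on a polygon boundary are retained.
#'
#' @param fixes an `argos_fixes` table.
#' @param mask list of polygon data.frames (`lon`, `lat`), a single polygon
#'   data.frame, or a path to a GeoJSON file.
#' @return the fixes with updated `retained`/`reason`.
#' @export
apply_landmask <- function(fixes, mask) {
  fixes <- as_argos_fixes(fixes)
  if (is.character(mask)) mask <- read_landmask(mask)
  if (is.data.frame(mask)) mask <- list(mask)
  idx <- which(fixes$retained)
  for (i in idx) {
    for (p in mask) {
      if (.point_in_polygon(fixes$lon[i], fixes$lat[i], p) == 2L) {
        fixes$retained[i] <- FALSE
        fixes$reason[i] <- "land"
        break
      }
    }
  }
  fixes
}

#' Sequential maximum-speed filter
#'
#' Removes fixes implying unsustainable travel speed. Per animal, while any
#' consecutive pair of retained fixes implies a speed above `vmax`, the
#' removable fix involved in a violating pair whose implied speed (the
#' larger of the speeds to its retained neighbours) is greatest is dropped;
#' among equal implied speeds the smaller of the two neighbour speeds
#' breaks the tie (so an isolated spike outranks its innocent neighbours),
#' and any remaining tie goes to the later fix. Class 3 fixes (smallest
#' stated ARGOS error) and the first and last fix of a track are never
#' removed. The result is a fixed point: re-filtering changes nothing.
#'
#' @param fixes an `argos_fixes` table.
#' @param vmax maximum sustained speed, km/h (default 8).
#' @param manual_reject optional data.frame (`animal_id`, `time`) of fixes to
#'   drop up front (`reason = "manual"`), standing in for visual inspection.
#' @return the fixes with updated `retained`/`reason`.
#' @export
speed_filter <- function(fixes, vmax = 8, manual_reject = NULL) {
  if (vmax <= 0) stop("vmax must be > 0")
  fixes <- as_argos_fixes(fixes)
  if (!is.null(manual_reject)) {
    key <- paste(fixes$animal_id, as.numeric(fixes$time))
    drop <- key %in% paste(manual_reject$animal_id,
                           as.numeric(manual_reject$time))
    fixes$retained[drop] <- FALSE
    fixes$reason[drop] <- "manual"
  }
  if (nrow(fixes) < 2) return(fixes)

  pair_speed <- function(i, j) {
    dt <- as.numeric(difftime(fixes$time[j], fixes$time[i], units = "hours"))
    d <- great_circle_distance(fixes$lat[i], fixes$lon[i],
                               fixes$lat[j], fixes$lon[j])
    if (dt <= 0) ifelse(d > 0, Inf, 0) else d / dt
  }

  for (id in unique(fixes$animal_id)) {
    rows <- which(fixes$animal_id == id)
    if (length(rows) < 2) next
    immune <- fixes$quality[rows] == "3"
    immune[c(1, length(rows))] <- TRUE
    keep <- fixes$retained[rows]
    repeat {
      act <- which(keep)
      if (length(act) < 2) break
      sp <- vapply(seq_len(length(act) - 1), function(k)
        pair_speed(rows[act[k]], rows[act[k + 1]]), numeric(1))
      bad <- which(sp > vmax)
      if (length(bad) == 0) break
      # fixes participating in violating pairs, excluding immune ones
      cand <- unique(c(act[bad], act[bad + 1]))
      cand <- cand[!immune[cand]]
      if (length(cand) == 0) break
      nbr <- vapply(cand, function(ci) {
        pos <- match(ci, act)
        s <- c(-Inf, -Inf)
        if (pos > 1) s[1] <- sp[pos - 1]
        if (pos < length(act)) s[2] <- sp[pos]
        c(max(s), min(s))
      }, numeric(2))
      best <- cand[nbr[1, ] == max(nbr[1, ])]
      if (length(best) > 1) {
        mins <- nbr[2, match(best, cand)]
        best <- best[mins == max(mins)]
      }
      drop <- max(best)  # remaining tie -> later fix
      keep[drop] <- FALSE
      fixes$reason[rows[drop]] <- "speed"
    }
    fixes$retained[rows] <- keep
  }
  fixes
}
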