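# Plain-text writers/readers for the synthetic field-data set. Times are
# ISO-8601 UTC throughout.

.fmt_time <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
.parse_time <- function(s) as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%SZ",
                                      tz = "UTC")

#' @rdname synthetic_io
#' @export
write_tide_csv <- function(series, path) {
  write.csv(data.frame(time = .fmt_time(series$time),
                       height_m = series$height_m),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname synthetic_io
#' @export
read_tide_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  out <- data.frame(time = .parse_time(d$time), height_m = d$height_m)
  class(out) <- c("tide_series", "data.frame")
  out
}

#' @rdname synthetic_io
#' @export
write_argos_csv <- function(fixes, path) {
  write.csv(data.frame(animal_id = fixes$animal_id,
                       time = .fmt_time(fixes$time),
                       lat = fixes$lat, lon = fixes$lon,
                       quality = fixes$quality),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname synthetic_io
#' @export
read_argos_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE,
                colClasses = c(quality = "character"))
  d$time <- .parse_time(d$time)
  as_argos_fixes(d)
}

#' @rdname synthetic_io
#' @export
write_tdr_csv <- function(series, path) {
  write.csv(data.frame(time = .fmt_time(series$time),
                       depth_m = series$depth_m),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname synthetic_io
#' @export
read_tdr_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  out <- data.frame(time = .parse_time(d$time), depth_m = d$depth_m)
  class(out) <- c("dive_series", "data.frame")
  attr(out, "corrected") <- FALSE
  out
}

#' @rdname synthetic_io
#' @export
write_glider_csv <- function(segments, path) {
  write.csv(data.frame(t0 = .fmt_time(segments$t0), t1 = .fmt_time(segments$t1),
                       lat_dr = segments$lat_dr, lon_dr = segments$lon_dr,
                       lat_gps = segments$lat_gps, lon_gps = segments$lon_gps),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname synthetic_io
#' @export
read_glider_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  d$t0 <- .parse_time(d$t0)
  d$t1 <- .parse_time(d$t1)
  class(d) <- c("glider_segments", "data.frame")
  d
}

#' @rdname synthetic_io
#' @export
write_wind_csv <- function(wind, path) {
  write.csv(data.frame(time = .fmt_time(wind$time),
                       speed_mps = wind$speed_mps),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname synthetic_io
#' @export
read_wind_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  d$time <- .parse_time(d$time)
  d
}

#' Synthetic data set I/O
#'
#' CSV writers and readers for every synthetic input (tide gauge, ARGOS
#' fixes, 1 Hz TDR, glider segments, wind), a GeoJSON land-mask writer, and
#' a JSON manifest recording the seed and configuration of a generated set.
#'
#' @param series,fixes,segments,wind data to write.
#' @param path file path.
#' @param config a [sim_config()] (manifest).
#' @param extra named list of additional manifest entries.
#' @name synthetic_io
#' @export
write_manifest <- function(config, path, extra = list()) {
  cfg <- unclass(config)
  cfg$current_field <- NULL
  cfg$land_polygon <- NULL
  jsonlite::write_json(c(list(package = "tideforage",
                              created = .fmt_time(Sys.time())),
                         cfg, extra),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Toy island polygon
#'
#' A closed convex ring (approximate circle on the sphere) used as a land
#' mask in simulations. This is a synthetic stand-in polygon, not a real
#' coastline.
#'
#' @param center_lat,center_lon island centre, decimal degrees.
#' @param radius_km island radius, km.
#' @param n number of vertices.
#' @return data.frame with `lon`, `lat`; first row equals the last (closed).
#' @export
toy_island <- function(center_lat, center_lon, radius_km = 0.6, n = 24) {
  brg <- seq(0, 360, length.out = n + 1)
  p <- destination_point(center_lat, center_lon, brg[-(n + 1)], radius_km)
  data.frame(lon = c(p$lon, p$lon[1]), lat = c(p$lat, p$lat[1]))
}

#' @rdname synthetic_io
#' @param polygons list of polygon data.frames (`lon`, `lat`, closed rings).
#' @export
write_landmask_geojson <- function(polygons, path) {
  if (is.data.frame(polygons)) polygons <- list(polygons)
  feats <- lapply(polygons, function(p) {
    ring <- lapply(seq_len(nrow(p)), function(i) c(p$lon[i], p$lat[i]))
    list(type = "Feature", properties = list(name = "land"),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a GeoJSON land mask
#'
#' Supports Polygon and MultiPolygon features; only outer rings are used.
#'
#' @param path GeoJSON file path.
#' @return list of polygon data.frames (`lon`, `lat`).
#' @export
read_landmask <- function(path) {
  g <- jsonlite::read_json(path)
  polys <- list()
  add_ring <- function(ring) {
    m <- do.call(rbind, lapply(ring, function(pt)
      c(as.numeric(pt[[1]]), as.numeric(pt[[2]]))))
    polys[[length(polys) + 1]] <<- data.frame(lon = m[, 1], lat = m[, 2])
  }
  for (f in g$features) {
    geom <- f$geometry
    if (geom$type == "Polygon") {
      add_ring(geom$coordinates[[1]])
    } else if (geom$type == "MultiPolygon") {
      for (pg in geom$coordinates) add_ring(pg[[1]])
    }
  }
  polys
}

#' Write a complete synthetic data set to a directory
#'
#' Generates tide, ARGOS, TDR, glider, wind and land-mask files plus a
#' manifest, all driven by one configuration and seed.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @param days length of the tide record, days.
#' @param constituents tidal constituent set.
#' @return invisibly, a named list of the file paths written.
#' @export
write_synthetic_set <- function(config, dir, days = 30,
                                constituents = default_constituents()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  tide <- gen_tide_series(constituents, days = days, noise_sd = 0.002,
                          seed = config$seed)
  paths$tide <- write_tide_csv(tide, file.path(dir, "tide.csv"))
  cal <- build_regime_calendar(tide)
  tracks <- gen_trips(config, cal)
  paths$argos <- write_argos_csv(tracks$argos, file.path(dir, "argos.csv"))
  trip1 <- tracks$true[tracks$true$trip == 1, ]
  tdr <- gen_dive_record(trip1, dive_depths = runif(8, 10, 80),
                         drift_rate = config$tdr_drift_m_per_min,
                         seed = config$seed + 1)
  paths$tdr <- write_tdr_csv(tdr, file.path(dir, "tdr.csv"))
  field <- config$current_field
  if (is.null(field)) field <- tidal_current_field(cal)
  wpt_c <- destination_point(config$colony_lat, config$colony_lon, 45, 8)
  wpts <- rbind(wpt_c, destination_point(wpt_c$lat, wpt_c$lon, 45, 4))
  segs <- gen_glider_mission(field, wpts, gps_noise_m = 10,
                             seed = config$seed + 2,
                             start = as.POSIXct(min(cal$date), tz = "UTC"),
                             duration_h = min(days, 21) * 24)
  paths$glider <- write_glider_csv(segs, file.path(dir, "glider.csv"))
  wind <- gen_wind_series(days = days, seed = config$seed + 3)
  paths$wind <- write_wind_csv(wind, file.path(dir, "wind.csv"))
  paths$landmask <- write_landmask_geojson(config$land_polygon,
                                           file.path(dir, "landmask.geojson"))
  paths$manifest <- write_manifest(config, file.path(dir, "manifest.json"),
                                   extra = list(days = days))
  invisible(paths)
}
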