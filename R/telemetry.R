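#' @keywords internal
"_PACKAGE"

DEG2RAD <- pi / 180
EARTH_RADIUS_KM <- 6371.0

.check_coords <- function(lat, lon) {
  if (!all(is.finite(lat)) || !all(is.finite(lon)))
    stop("non-finite coordinates", call. = FALSE)
  if (any(lat < -90 | lat > 90))
    stop("latitude outside [-90, 90]", call. = FALSE)
  if (any(lon < -180 | lon > 180))
    stop("longitude outside [-180, 180]", call. = FALSE)
  invisible(TRUE)
}

#' Great-circle distance between GPS fixes
#'
#' Haversine distance on a spherical Earth. Vectorized over all four
#' coordinate arguments.
#'
#' @param lat1,lon1 coordinates of the first fix, decimal degrees.
#' @param lat2,lon2 coordinates of the second fix, decimal degrees.
#' @param radius_km sphere radius in kilometres (default mean Earth radius).
#' @return distance in kilometres, bounded by `pi * radius_km`.
#' @examples
#' haversine_distance(0, 0, 1, 0)  # one degree of latitude, ~111.19 km
#' @export
haversine_distance <- function(lat1, lon1, lat2, lon2,
                               radius_km = EARTH_RADIUS_KM) {
  stopifnot(radius_km > 0)
  .check_coords(lat1, lon1)
  .check_coords(lat2, lon2)
  p1 <- lat1 * DEG2RAD; p2 <- lat2 * DEG2RAD
  dphi <- (lat2 - lat1) * DEG2RAD
  dlam <- (lon2 - lon1) * DEG2RAD
  a <- sin(dphi / 2)^2 + cos(p1) * cos(p2) * sin(dlam / 2)^2
  2 * radius_km * asin(pmin(1, sqrt(pmax(a, 0))))
}

#' Central-difference speed at the middle of three fixes
#'
#' Speed assigned to the fix between `p1` and `p3`: great-circle distance
#' from `p1` to `p3` divided by their time separation, in kph.
#'
#' @param lat1,lon1,t1 first fix (degrees, seconds).
#' @param lat3,lon3,t3 third fix (degrees, seconds); `t3` must exceed `t1`.
#' @param radius_km sphere radius in kilometres.
#' @return speed in kilometres per hour.
#' @export
central_speed <- function(lat1, lon1, t1, lat3, lon3, t3,
                          radius_km = EARTH_RADIUS_KM) {
  dt <- t3 - t1
  if (any(dt <= 0)) stop("time interval must be positive", call. = FALSE)
  haversine_distance(lat1, lon1, lat3, lon3, radius_km) / dt * 3600
}

#' Forward azimuth between two GPS fixes
#'
#' Initial great-circle bearing from the first fix to the second:
#' 0 = North, 90 = East, increasing clockwise, in [0, 360).
#' Coincident fixes have no bearing and yield `NA`.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (vectorized).
#' @return bearing in degrees, or `NA` where the fixes coincide.
#' @export
bearing <- function(lat1, lon1, lat2, lon2) {
  .check_coords(lat1, lon1)
  .check_coords(lat2, lon2)
  p1 <- lat1 * DEG2RAD; p2 <- lat2 * DEG2RAD
  dlam <- (lon2 - lon1) * DEG2RAD
  y <- sin(dlam) * cos(p2)
  x <- cos(p1) * sin(p2) - sin(p1) * cos(p2) * cos(dlam)
  b <- (atan2(y, x) / DEG2RAD) %% 360
  b[lat1 == lat2 & lon1 == lon2] <- NA_real_
  b
}

#' Map an azimuth onto the unit circle
#'
#' Compass direction suffers a discontinuity at North (0 or 360 degrees).
#' Mapping the angle to its unit-circle coordinates removes it:
#' North -> (0, 1), East -> (1, 0), South -> (0, -1), West -> (-1, 0).
#' Undefined azimuths (`NA`, e.g. a stationary fix or the last point of a
#' trip) map to the (0, 0) sentinel.
#'
#' @param azimuth_deg compass bearing in degrees, 0..360 (vectorized).
#' @return two-column matrix with columns `azimuth_x` (east component,
#'   `sin`) and `azimuth_y` (north component, `cos`).
#' @examples
#' azimuth_to_unit_circle(c(0, 90, 180, 270, 360))
#' @export
azimuth_to_unit_circle <- function(azimuth_deg) {
  if (any(azimuth_deg < 0 | azimuth_deg > 360, na.rm = TRUE))
    stop("azimuth outside [0, 360]", call. = FALSE)
  theta <- (azimuth_deg %% 360) * DEG2RAD
  ax <- sin(theta)
  ay <- cos(theta)
  ax[is.na(azimuth_deg)] <- 0
  ay[is.na(azimuth_deg)] <- 0
  cbind(azimuth_x = ax, azimuth_y = ay)
}

#' Derive the naive telemetry feature table for one trip
#'
#' Augments a trip of raw per-second GPS fixes with the tabular-stream
#' features: step distance to the next fix (km), central-difference speed
#' (kph, one-sided at the trip ends), speed over ground (imputed from the
#' computed speed where missing and flagged), azimuth of travel and its
#' unit-circle components. The last fix has no successor and carries the
#' (0, 0) direction sentinel, as do stationary steps.
#'
#' @param trip data.frame with columns `timestamp` (seconds, strictly
#'   increasing), `lat`, `lon`, and optionally `sog_kph`. Other columns
#'   (e.g. `driver_id`, `trip_id`) are passed through.
#' @param radius_km Earth radius in kilometres.
#' @return the input with columns `step_distance_km`, `speed_kph`,
#'   `sog_kph`, `sog_imputed`, `azimuth_deg`, `azimuth_x`, `azimuth_y`
#'   appended; one row per input fix.
#' @export
build_feature_table <- function(trip, radius_km = EARTH_RADIUS_KM) {
  stopifnot(is.data.frame(trip),
            all(c("timestamp", "lat", "lon") %in% names(trip)))
  n <- nrow(trip)
  if (n < 3) stop("trip too short: need at least 3 fixes", call. = FALSE)
  ts <- trip$timestamp
  if (any(diff(ts) <= 0))
    stop("timestamps must be strictly increasing within a trip", call. = FALSE)
  .check_coords(trip$lat, trip$lon)

  lat <- trip$lat; lon <- trip$lon
  i <- seq_len(n - 1)
  step <- numeric(n)
  step[i] <- haversine_distance(lat[i], lon[i], lat[i + 1], lon[i + 1],
                                radius_km)
  step[n] <- 0

  speed <- numeric(n)
  mid <- 2:(n - 1)
  speed[mid] <- central_speed(lat[mid - 1], lon[mid - 1], ts[mid - 1],
                              lat[mid + 1], lon[mid + 1], ts[mid + 1],
                              radius_km)
  speed[1] <- step[1] / (ts[2] - ts[1]) * 3600
  speed[n] <- step[n - 1] / (ts[n] - ts[n - 1]) * 3600

  az <- rep(NA_real_, n)
  az[i] <- bearing(lat[i], lon[i], lat[i + 1], lon[i + 1])
  uc <- azimuth_to_unit_circle(az)

  if (is.null(trip$sog_kph)) {
    sog <- speed
    imputed <- rep(TRUE, n)
  } else {
    sog <- trip$sog_kph
    imputed <- !is.finite(sog)
    sog[imputed] <- speed[imputed]
  }

  out <- trip
  out$step_distance_km <- step
  out$speed_kph <- speed
  out$sog_kph <- sog
  out$sog_imputed <- imputed
  out$azimuth_deg <- az
  out$azimuth_x <- uc[, "azimuth_x"]
  out$azimuth_y <- uc[, "azimuth_y"]
  out
}

#' Featurize a multi-driver telemetry table
#'
#' Applies [build_feature_table()] independently to every
#' (`driver_id`, `trip_id`) trip in a cohort telemetry table.
#'
#' @param telemetry data.frame with columns `driver_id`, `trip_id`,
#'   `timestamp`, `lat`, `lon` and optionally `sog_kph`.
#' @param radius_km Earth radius in kilometres.
#' @return one feature row per input fix, trips kept contiguous.
#' @export
featurize_cohort <- function(telemetry, radius_km = EARTH_RADIUS_KM) {
  stopifnot(all(c("driver_id", "trip_id") %in% names(telemetry)))
  key <- paste(telemetry$driver_id, telemetry$trip_id, sep = "\r")
  parts <- split(telemetry, factor(key, levels = unique(key)))
  out <- lapply(parts, build_feature_table, radius_km = radius_km)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read / write the telemetry CSV schema
#'
#' The on-disk schema is `driver_id,trip_id,timestamp,lat,lon,sog_kph`
#' with a header row; `sog_kph` may be blank. [write_telemetry()] drops
#' simulator-internal columns (e.g. the injected-episode annotation).
#'
#' @param path file path.
#' @return [read_telemetry()]: a data.frame in the schema above.
#' @export
read_telemetry <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("driver_id", "trip_id", "timestamp", "lat", "lon")
  if (!all(need %in% names(df)))
    stop("telemetry CSV missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  df
}

#' @rdname read_telemetry
#' @param telemetry data.frame to write.
#' @export
write_telemetry <- function(telemetry, path) {
  cols <- intersect(c("driver_id", "trip_id", "timestamp", "lat", "lon",
                      "sog_kph"), names(telemetry))
  utils::write.csv(telemetry[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_telemetry
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("driver_id", "label") %in% names(df)))
  df
}

#' @rdname read_labels
#' @param labels data.frame with `driver_id`, `label`.
#' @export
write_labels <- function(labels, path) {
  utils::write.csv(labels[, c("driver_id", "label")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
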