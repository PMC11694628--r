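test_that("haversine distance matches closed forms and an independent oracle", {
  # identity and antipodal closed forms
  expect_equal(haversine_distance(12.3, 45.6, 12.3, 45.6), 0)
  expect_equal(haversine_distance(0, 0, 0, 180), pi * 6371)
  # one-degree meridian arc: closed form r * dphi
  expect_equal(haversine_distance(0, 0, 1, 0), 6371 * pi / 180,
               tolerance = 1e-10)
  # spherical law of cosines as an independent route to the same quantity
  sloc <- function(lat1, lon1, lat2, lon2, r = 6371) {
    p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
    dl <- (lon2 - lon1) * pi / 180
    r * acos(pmin(1, sin(p1) * sin(p2) + cos(p1) * cos(p2) * cos(dl)))
  }
  expect_equal(haversine_distance(0, 0, 1, 0), sloc(0, 0, 1, 0),
               tolerance = 1e-9)
  expect_equal(haversine_distance(40, -75, 41, -74.2),
               sloc(40, -75, 41, -74.2), tolerance = 1e-9)
  # custom radius flows through linearly
  expect_equal(haversine_distance(0, 0, 1, 0, radius_km = 1000),
               1000 * pi / 180, tolerance = 1e-10)
  expect_error(haversine_distance(NaN, 0, 1, 0), "non-finite")
  expect_error(haversine_distance(95, 0, 1, 0), "latitude")
})

test_that("haversine distance agrees with geosphere on random fix pairs", {
  skip_if_not_installed("geosphere")
  set.seed(1)
  lat1 <- runif(50, -80, 80); lon1 <- runif(50, -179, 179)
  lat2 <- runif(50, -80, 80); lon2 <- runif(50, -179, 179)
  ours <- haversine_distance(lat1, lon1, lat2, lon2)
  ref <- geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                                  r = 6371)
  expect_equal(ours, ref, tolerance = 1e-9)
})

test_that("haversine is symmetric and satisfies the triangle inequality", {
  set.seed(42)
  for (i in 1:200) {
    a <- c(runif(1, -85, 85), runif(1, -180, 180))
    b <- c(runif(1, -85, 85), runif(1, -180, 180))
    d_ab <- haversine_distance(a[1], a[2], b[1], b[2])
    d_ba <- haversine_distance(b[1], b[2], a[1], a[2])
    expect_identical(d_ab, d_ba)
  }
  for (i in 1:200) {
    p <- matrix(c(runif(3, -85, 85), runif(3, -180, 180)), ncol = 2)
    d12 <- haversine_distance(p[1, 1], p[1, 2], p[2, 1], p[2, 2])
    d23 <- haversine_distance(p[2, 1], p[2, 2], p[3, 1], p[3, 2])
    d13 <- haversine_distance(p[1, 1], p[1, 2], p[3, 1], p[3, 2])
    expect_lte(d13, d12 + d23 + 1e-9)
  }
})

test_that("central speed follows distance over time and shifts with the clock", {
  # no displacement
  expect_equal(central_speed(10, 20, 0, 10, 20, 2), 0)
  # 0.02 km in 2 s = 36 kph
  d1 <- 0.02 / (6371 * pi / 180)  # degrees of latitude spanning 0.02 km
  expect_equal(central_speed(0, 0, 0, d1, 0, 2), 36, tolerance = 1e-9)
  # meridian step of 2 arc-seconds over 2 s: one arc-second per second,
  # i.e. the meridian-arc oracle 6371*pi/180 km/h / 3600 scaled back up
  v <- central_speed(0, 0, 0, 2 / 3600, 0, 2)
  expect_equal(v, 6371 * pi / 180, tolerance = 1e-9)
  # invariance under shifting both timestamps
  expect_identical(central_speed(0, 0, 5, d1, 0, 7),
                   central_speed(0, 0, 1005, d1, 0, 1007))
  expect_error(central_speed(0, 0, 5, 1, 0, 5), "positive")
})

test_that("bearing honours the compass convention", {
  expect_equal(bearing(0, 0, 1, 0), 0)            # due north
  expect_equal(bearing(0, 0, 0, 1), 90)           # due east at the equator
  expect_equal(bearing(1, 0, 0, 0), 180)          # due south
  expect_equal(bearing(0, 1, 0, 0), 270)          # due west
  # small equal-offset step with cos-lat-scaled longitude ~ 45 degrees,
  # against the independent planar arctangent
  lat0 <- 40
  dlat <- 1e-4
  dlon <- 1e-4 / cos(lat0 * pi / 180)
  planar <- atan2(dlon * cos(lat0 * pi / 180), dlat) * 180 / pi
  expect_equal(bearing(lat0, 10, lat0 + dlat, 10 + dlon), planar,
               tolerance = 1e-3)
  expect_true(is.na(bearing(10, 20, 10, 20)))     # coincident fixes
})

test_that("unit-circle mapping hits the cardinal anchors and stays on the circle", {
  m <- azimuth_to_unit_circle(c(0, 90, 180, 270, 360, 45))
  expect_equal(m[1, ], c(azimuth_x = 0, azimuth_y = 1))
  expect_equal(m[2, ], c(azimuth_x = 1, azimuth_y = 0), tolerance = 1e-12)
  expect_equal(m[3, ], c(azimuth_x = 0, azimuth_y = -1), tolerance = 1e-12)
  expect_equal(m[4, ], c(azimuth_x = -1, azimuth_y = 0), tolerance = 1e-12)
  # 0 and 360 map identically, removing the North discontinuity
  expect_identical(m[5, ], m[1, ])
  expect_equal(m[6, ], c(azimuth_x = sqrt(2) / 2, azimuth_y = sqrt(2) / 2))
  # unit norm everywhere it is defined
  az <- seq(0, 360, by = 0.25)
  uc <- azimuth_to_unit_circle(az)
  expect_equal(rowSums(uc^2), rep(1, length(az)), tolerance = 1e-12)
  # sentinel for undefined azimuth
  expect_equal(unname(azimuth_to_unit_circle(NA_real_)[1, ]), c(0, 0))
  expect_error(azimuth_to_unit_circle(400), "azimuth")
})

test_that("feature table has one record per fix with sane boundary handling", {
  trip <- make_east_trip(n = 13)
  ft <- build_feature_table(trip)
  expect_equal(nrow(ft), 13)
  # all but the last fix head due east
  expect_equal(ft$azimuth_deg[1:12], rep(90, 12), tolerance = 1e-4)
  expect_equal(ft$azimuth_x[1:12], rep(1, 12), tolerance = 1e-6)
  expect_equal(ft$azimuth_y[1:12], rep(0, 12), tolerance = 1e-3)
  # last fix: no successor, direction sentinel and zero step
  expect_equal(ft$azimuth_x[13], 0)
  expect_equal(ft$azimuth_y[13], 0)
  expect_equal(ft$step_distance_km[13], 0)
  # constant speed: interior central differences equal the step rate
  expect_equal(stats::sd(ft$speed_kph[2:12]), 0, tolerance = 1e-9)
  # SOG missing entirely: imputed from computed speed and flagged
  expect_true(all(ft$sog_imputed))
  expect_equal(ft$sog_kph, ft$speed_kph)
})

test_that("feature table handles stationary trips and rejects bad input", {
  ft <- build_feature_table(make_stationary_trip(n = 6))
  expect_true(all(ft$step_distance_km == 0))
  expect_true(all(ft$speed_kph == 0))
  expect_true(all(ft$azimuth_x == 0 & ft$azimuth_y == 0))
  expect_error(build_feature_table(make_east_trip(n = 2)), "too short")
  bad <- make_east_trip(5); bad$timestamp[3] <- bad$timestamp[2]
  expect_error(build_feature_table(bad), "increasing")
  # partial SOG: only missing entries imputed
  trip <- make_east_trip(5)
  trip$sog_kph <- c(30, NA, 31, NA, 29)
  ft2 <- build_feature_table(trip)
  expect_equal(ft2$sog_kph[c(1, 3, 5)], c(30, 31, 29))
  expect_equal(ft2$sog_imputed, c(FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(ft2$sog_kph[2], ft2$speed_kph[2])
})

test_that("telemetry CSV round-trips through the documented schema", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  trip <- make_east_trip(5)
  trip$driver_id <- "d001"; trip$trip_id <- 1L
  trip$sog_kph <- 30; trip$episode <- "none"
  write_telemetry(trip, tmp)
  back <- read_telemetry(tmp)
  expect_named(back, c("driver_id", "trip_id", "timestamp", "lat", "lon",
                       "sog_kph"))
  expect_equal(back$lat, trip$lat)
  expect_null(back$episode)
})
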