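#' Driving phenotype parameters
#'
#' Kinematic parameters of a simulated driver class. The abnormal
#' phenotype injects anomalous episodes with the stated probabilities;
#' the rest of an abnormal driver's time behaves normally, so abnormal
#' drivers emit a mixture of normal and anomalous stretches (the
#' weak-label structure the classifier must cope with).
#'
#' Episode types: `erratic` (large oscillatory speed swings), `hesitation`
#' (an unexplained mid-block near-stop), `wander` (a navigation failure:
#' a jog onto the parallel street and back, a block-circling loop, a
#' staircase of alternating missed-turn corrections, or a U-turn
#' backtrack — detours that leave distinctive occupancy shapes). The
#' default abnormal phenotype is navigation-dominant, reflecting
#' wayfinding difficulty as the hallmark impaired-driving sign.
#'
#' @param label 0 (normal) or 1 (abnormal).
#' @param base_speed_kph mean cruise speed.
#' @param speed_jitter_kph standard deviation of the smooth AR(1) speed
#'   wander around the base.
#' @param turn_rate_per_km expected ordinary turns per km of travel.
#' @param erratic_prob,hesitation_prob,wander_prob probability that a
#'   given episode is of the named anomalous type; their sum must be at
#'   most 1. Episodes span 10–60 s (wander 30–60 s, long enough to fill
#'   an analysis window).
#' @return a `phenotype_params` list.
#' @export
phenotype_params <- function(label, base_speed_kph = 40,
                             speed_jitter_kph = 2, turn_rate_per_km = 2,
                             erratic_prob = 0, hesitation_prob = 0,
                             wander_prob = 0) {
  p <- c(erratic_prob, hesitation_prob, wander_prob)
  stopifnot(label %in% c(0, 1), base_speed_kph > 0,
            all(p >= 0), sum(p) <= 1)
  structure(list(label = as.integer(label),
                 base_speed_kph = base_speed_kph,
                 speed_jitter_kph = speed_jitter_kph,
                 turn_rate_per_km = turn_rate_per_km,
                 erratic_prob = erratic_prob,
                 hesitation_prob = hesitation_prob,
                 wander_prob = wander_prob),
            class = "phenotype_params")
}

#' @rdname phenotype_params
#' @export
normal_phenotype <- function() phenotype_params(label = 0)

#' @rdname phenotype_params
#' @export
abnormal_phenotype <- function() {
  phenotype_params(label = 1, speed_jitter_kph = 3,
                   erratic_prob = 0.05, hesitation_prob = 0.10,
                   wander_prob = 0.60)
}

#' Cohort simulation configuration
#'
#' Desk-scale stand-in for a multi-year telematics cohort: a handful of
#' drivers, a few short trips each, sampled at 1 Hz on a Manhattan-style
#' street lattice around a fixed origin.
#'
#' @param n_drivers total drivers (>= 2 when both labels present).
#' @param abnormal_fraction fraction of drivers labeled abnormal.
#' @param trips_per_driver trips recorded per driver.
#' @param trip_duration_s seconds per trip (1 Hz sampling).
#' @param origin_lat,origin_lon lattice origin in degrees.
#' @param block_km city-block edge length in km.
#' @param gps_noise_km GPS position jitter std in km.
#' @param sog_noise_kph speed-over-ground sensor noise std in kph.
#' @param seed RNG seed for the whole cohort.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_drivers = 20L, abnormal_fraction = 0.5,
                              trips_per_driver = 2L, trip_duration_s = 240L,
                              origin_lat = 40.75, origin_lon = -73.99,
                              block_km = 0.1, gps_noise_km = 0.003,
                              sog_noise_kph = 1, seed = 1L) {
  stopifnot(n_drivers >= 1, abnormal_fraction >= 0, abnormal_fraction <= 1,
            trips_per_driver >= 1, trip_duration_s >= 3, block_km > 0)
  if (abnormal_fraction > 0 && abnormal_fraction < 1 && n_drivers < 2)
    stop("need at least 2 drivers to carry both labels", call. = FALSE)
  structure(list(n_drivers = as.integer(n_drivers),
                 abnormal_fraction = abnormal_fraction,
                 trips_per_driver = as.integer(trips_per_driver),
                 trip_duration_s = as.integer(trip_duration_s),
                 sample_hz = 1L,
                 origin_lat = origin_lat, origin_lon = origin_lon,
                 block_km = block_km, gps_noise_km = gps_noise_km,
                 sog_noise_kph = sog_noise_kph, seed = as.integer(seed)),
            class = "simulation_config")
}

# Partition a trip's timeline into 10-60 s episodes and draw each one's
# type from the phenotype's episode probabilities.
.draw_episodes <- function(total_s, phenotype) {
  types <- c("erratic", "hesitation", "wander")
  probs <- c(phenotype$erratic_prob, phenotype$hesitation_prob,
             phenotype$wander_prob)
  out <- list()
  t0 <- 1L
  while (t0 <= total_s) {
    type <- sample(c(types, "none"), 1, prob = c(probs, 1 - sum(probs)))
    # wandering detours play out over longer stretches than momentary
    # speed anomalies
    len <- if (identical(type, "wander")) sample(30:60, 1) else
      sample(10:60, 1)
    end <- min(t0 + len - 1L, total_s)
    out[[length(out) + 1L]] <- list(start = t0, end = end, type = type)
    t0 <- end + 1L
  }
  out
}

#' Simulate one trip of per-second GPS fixes
#'
#' A vehicle drives an axis-aligned street lattice: it cruises at the
#' phenotype's base speed with smooth AR(1) variation, turning left or
#' right at intersections with a probability set by the turn rate.
#' Anomalous episodes (abnormal phenotype) overlay large speed
#' oscillations, mid-block near-stops, or forced turn patterns that
#' produce parallel-street jogs, loops, staircase weaves and U-turn
#' backtracks. Positions receive
#' Gaussian GPS jitter and the reported speed over ground is the true
#' speed plus sensor noise.
#'
#' Uses the ambient RNG stream; seed via [simulate_cohort()] or
#' `set.seed()` for reproducibility.
#'
#' @param phenotype a [phenotype_params()].
#' @param cfg a [simulation_config()].
#' @param driver_id,trip_id identifiers stamped on the output rows.
#' @return data.frame with columns `driver_id`, `trip_id`, `timestamp`,
#'   `lat`, `lon`, `sog_kph`, and the simulator-internal `episode`
#'   annotation (dropped by [write_telemetry()]).
#' @export
simulate_trip <- function(phenotype, cfg = simulation_config(),
                          driver_id = "d01", trip_id = 1L) {
  T_s <- cfg$trip_duration_s
  if (T_s < 3) stop("trip too short: need at least 3 seconds", call. = FALSE)
  B <- cfg$block_km
  base <- phenotype$base_speed_kph

  episodes <- .draw_episodes(T_s, phenotype)
  ep_type <- character(T_s)
  hes_window <- logical(T_s)
  wander_mode <- character(T_s)
  uturn_at <- integer(0)
  for (e in episodes) {
    span <- e$start:e$end
    ep_type[span] <- e$type
    if (e$type == "hesitation") {
      mid <- e$start + (e$end - e$start) %/% 2
      hes_window[max(e$start, mid - 3):min(e$end, mid + 3)] <- TRUE
    }
    if (e$type == "wander") {
      mode <- sample(c("jog", "loop", "weave", "backtrack"),
                     1, prob = c(0.6, 0.15, 0.15, 0.1))
      wander_mode[span] <- mode
      if (mode == "backtrack")
        uturn_at <- c(uturn_at, sample(span, 1))
    }
  }

  p_turn <- min(0.9, phenotype$turn_rate_per_km * B)
  heading <- sample(c(0, 90, 180, 270), 1)
  loop_dir <- 1
  weave_dir <- 1
  jog_phase <- 0L  # cycles R,L,L,R: out to the parallel street and back
  x <- numeric(T_s); y <- numeric(T_s)
  speed <- numeric(T_s)
  px <- 0; py <- 0
  ar <- 0
  ar_sd <- phenotype$speed_jitter_kph * sqrt(1 - 0.9^2)
  for (t in seq_len(T_s)) {
    ar <- 0.9 * ar + stats::rnorm(1, sd = ar_sd)
    v <- base + ar
    if (ep_type[t] == "erratic")
      v <- base + 0.8 * base * sin(2 * pi * t / 7) + ar
    if (hes_window[t]) v <- 2
    v <- max(0, v)
    speed[t] <- v
    if (t %in% uturn_at) heading <- (heading + 180) %% 360
    d <- v / 3600  # km this second
    while (d > 0) {
      ux <- sin(heading * pi / 180)
      uy <- cos(heading * pi / 180)
      # distance to the next intersection along the travel axis
      s_along <- if (ux != 0) px * ux else py * uy
      to_int <- B - (s_along %% B)
      if (to_int <= 1e-9) to_int <- B
      if (d < to_int) {
        px <- px + ux * d; py <- py + uy * d
        d <- 0
      } else {
        px <- px + ux * to_int; py <- py + uy * to_int
        d <- d - to_int
        if (wander_mode[t] == "jog") {
          # detour one block onto the parallel street and return: the
          # sideways legs cancel in the mean direction but leave a bump
          # on the occupancy grid
          turn <- c(90, -90, -90, 90)[jog_phase + 1L]
          heading <- (heading + turn) %% 360
          jog_phase <- (jog_phase + 1L) %% 4L
        } else if (wander_mode[t] == "loop") {
          if (stats::runif(1) < 0.9) heading <- (heading + 90 * loop_dir) %% 360
        } else if (wander_mode[t] == "weave") {
          # missed-turn corrections: forced alternating turns leave a
          # staircase shape on the grid
          heading <- (heading + 90 * weave_dir) %% 360
          weave_dir <- -weave_dir
        } else if (stats::runif(1) < p_turn) {
          heading <- (heading + sample(c(-90, 90), 1)) %% 360
        }
      }
    }
    x[t] <- px; y[t] <- py
  }

  kscale <- EARTH_RADIUS_KM * DEG2RAD  # km per degree of latitude
  lat <- cfg$origin_lat + (y + stats::rnorm(T_s, sd = cfg$gps_noise_km)) /
    kscale
  lon <- cfg$origin_lon +
    (x + stats::rnorm(T_s, sd = cfg$gps_noise_km)) /
    (kscale * cos(cfg$origin_lat * DEG2RAD))
  sog <- pmax(0, speed + stats::rnorm(T_s, sd = cfg$sog_noise_kph))

  data.frame(driver_id = driver_id, trip_id = trip_id,
             timestamp = seq_len(T_s), lat = lat, lon = lon,
             sog_kph = round(sog, 3), episode = ep_type,
             stringsAsFactors = FALSE)
}

#' Simulate a labeled driver cohort
#'
#' Generates `n_drivers` drivers, the configured fraction of them drawn
#' from the abnormal phenotype, each contributing `trips_per_driver`
#' trips. Every segment later derived from an abnormal driver inherits
#' label 1 regardless of whether its particular stretch contained an
#' anomalous episode — the weak-labeling rule under which the classifier
#' must learn from the frequency and pattern of anomalies.
#'
#' @param cfg a [simulation_config()]; `cfg$seed` fixes the whole cohort.
#' @param normal,abnormal [phenotype_params()] for the two classes.
#' @return list with `telemetry` (per-second fixes, all drivers),
#'   `labels` (`driver_id`, `label`), and `manifest` (all parameters and
#'   the seed, serializable to JSON).
#' @export
simulate_cohort <- function(cfg = simulation_config(),
                            normal = normal_phenotype(),
                            abnormal = abnormal_phenotype()) {
  set.seed(cfg$seed)
  n_ab <- round(cfg$n_drivers * cfg$abnormal_fraction)
  labels <- c(rep(0L, cfg$n_drivers - n_ab), rep(1L, n_ab))
  ids <- sprintf("d%03d", seq_len(cfg$n_drivers))
  trips <- list()
  for (i in seq_len(cfg$n_drivers)) {
    ph <- if (labels[i] == 1L) abnormal else normal
    for (j in seq_len(cfg$trips_per_driver)) {
      trips[[length(trips) + 1L]] <-
        simulate_trip(ph, cfg, driver_id = ids[i], trip_id = j)
    }
  }
  telemetry <- do.call(rbind, trips)
  rownames(telemetry) <- NULL
  list(telemetry = telemetry,
       labels = data.frame(driver_id = ids, label = labels,
                           stringsAsFactors = FALSE),
       manifest = c(unclass(cfg),
                    list(normal = unclass(normal),
                         abnormal = unclass(abnormal))))
}
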