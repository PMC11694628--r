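#' Build the segment-level training dataset
#'
#' Runs the full representation pipeline over a featurized cohort: slide
#' a `window`-record window along every trip (step `stride`), summarize
#' each window's tabular features as per-feature means, and rasterize
#' each window's path — shift-to-origin, integer grid indices at
#' `cell_km` resolution, `extent` x `extent` binary occupancy — for the
#' convolutional stream. Segments whose path cannot fit the extent are
#' counted in `n_overflow` and dropped, not clipped. Every segment
#' inherits its driver's label (weak labeling).
#'
#' The east-west projection scale is fixed at the cohort's first fix
#' (`ref_lat`), making the grid representation exactly
#' translation-invariant across the dataset.
#'
#' @param features output of [featurize_cohort()].
#' @param labels data.frame with `driver_id`, `label` (0/1).
#' @param window segment length in records.
#' @param cell_km grid cell edge in km.
#' @param extent occupancy grid cells per side.
#' @param stride sliding step in records.
#' @param ref_lat reference latitude for the east-west scale; default the
#'   first fix of the dataset.
#' @param naive_features `"unit_circle"` (default, 5 features: mean step
#'   distance, speed, SOG, azimuth_x, azimuth_y) or `"strict4"` (4
#'   features, direction as mean azimuth scaled to [0, 1]).
#' @return a `dg_dataset` list: `x_naive` (n x p), `x_grid` (n x
#'   extent^2, x fastest within y), `y`, `driver_id`, `trip_id`,
#'   `start_index`, `has_episode` (when the simulator annotation is
#'   present), plus the pipeline parameters and overflow count.
#' @export
build_segment_dataset <- function(features, labels, window = 13L,
                                  cell_km = 1, extent = 3L, stride = 1L,
                                  ref_lat = NULL,
                                  naive_features = c("unit_circle",
                                                     "strict4")) {
  naive_features <- match.arg(naive_features)
  if (is.null(ref_lat)) ref_lat <- features$lat[1]
  lab <- stats::setNames(as.integer(labels$label), labels$driver_id)
  key <- paste(features$driver_id, features$trip_id, sep = "\r")
  parts <- split(features, factor(key, levels = unique(key)))

  xn <- list(); xg <- list(); y <- integer(0)
  drv <- character(0); trp <- character(0); sidx <- integer(0)
  epi <- logical(0)
  n_overflow <- 0L
  has_epi_col <- "episode" %in% names(features)

  for (trip in parts) {
    segs <- segment_trajectory(trip, window, stride)
    for (seg in segs) {
      loc <- shift_to_origin(seg, ref_lat = ref_lat)
      idx <- assign_grid_indices(loc, cell_km)
      m <- rasterize_occupancy(idx, extent)
      if (is.null(m)) {
        n_overflow <- n_overflow + 1L
        next
      }
      if (naive_features == "unit_circle") {
        v <- c(dist = mean(seg$step_distance_km),
               speed = mean(seg$speed_kph),
               sog = mean(seg$sog_kph),
               azimuth_x = mean(seg$azimuth_x),
               azimuth_y = mean(seg$azimuth_y))
      } else {
        v <- c(dist = mean(seg$step_distance_km),
               speed = mean(seg$speed_kph),
               sog = mean(seg$sog_kph),
               azimuth = mean(seg$azimuth_deg, na.rm = TRUE) / 360)
        if (!is.finite(v[["azimuth"]])) v[["azimuth"]] <- 0
      }
      xn[[length(xn) + 1L]] <- v
      xg[[length(xg) + 1L]] <- as.vector(t(m))
      drv <- c(drv, seg$driver_id[1])
      trp <- c(trp, as.character(seg$trip_id[1]))
      sidx <- c(sidx, attr(seg, "start_index"))
      y <- c(y, lab[[seg$driver_id[1]]])
      if (has_epi_col) epi <- c(epi, any(seg$episode != "none"))
    }
  }
  structure(list(x_naive = do.call(rbind, xn),
                 x_grid = do.call(rbind, xg),
                 y = y, driver_id = drv, trip_id = trp,
                 start_index = sidx,
                 has_episode = if (has_epi_col) epi else NULL,
                 window = as.integer(window), cell_km = cell_km,
                 extent = as.integer(extent), stride = as.integer(stride),
                 ref_lat = ref_lat, naive_features = naive_features,
                 n_overflow = n_overflow),
            class = "dg_dataset")
}

#' Row-subset a segment dataset
#'
#' @param ds a `dg_dataset`.
#' @param rows integer or logical row selector.
#' @return the subset `dg_dataset`.
#' @export
subset_dataset <- function(ds, rows) {
  ds$x_naive <- ds$x_naive[rows, , drop = FALSE]
  ds$x_grid <- ds$x_grid[rows, , drop = FALSE]
  ds$y <- ds$y[rows]
  ds$driver_id <- ds$driver_id[rows]
  ds$trip_id <- ds$trip_id[rows]
  ds$start_index <- ds$start_index[rows]
  if (!is.null(ds$has_episode)) ds$has_episode <- ds$has_episode[rows]
  ds
}

# Rotate the mean direction features consistently with a CCW grid
# rotation so the two streams stay geometrically aligned.
.rotate_naive <- function(xn, angle, naive_features) {
  if (naive_features == "unit_circle") {
    ax <- xn[, "azimuth_x"]; ay <- xn[, "azimuth_y"]
    r <- switch(as.character(angle),
                "90"  = cbind(-ay, ax),
                "180" = cbind(-ax, -ay),
                "270" = cbind(ay, -ax))
    xn[, "azimuth_x"] <- r[, 1]
    xn[, "azimuth_y"] <- r[, 2]
  } else {
    xn[, "azimuth"] <- ((xn[, "azimuth"] * 360 - angle) %% 360) / 360
  }
  xn
}

#' Rotation-augment the rows of a segment dataset
#'
#' Appends the 90/180/270-degree CCW rotations of every selected row:
#' the occupancy grid is rotated (and re-anchored) and the mean direction
#' components co-rotate. Labels and grouping fields are carried over, so
#' the selected portion grows fourfold. Applied by [cross_validate()] to
#' training folds only.
#'
#' @param ds a `dg_dataset`.
#' @param rows rows to augment (default all).
#' @return the dataset with rotated copies appended.
#' @export
augment_dataset <- function(ds, rows = seq_along(ds$y)) {
  G <- ds$extent
  base <- subset_dataset(ds, rows)
  out_n <- list(base$x_naive)
  out_g <- list(base$x_grid)
  for (angle in c(90, 180, 270)) {
    rg <- base$x_grid
    for (i in seq_len(nrow(rg))) {
      m <- matrix(base$x_grid[i, ], nrow = G, ncol = G, byrow = TRUE)
      rg[i, ] <- as.vector(t(rotate_occupancy(m, angle)))
    }
    out_g[[length(out_g) + 1L]] <- rg
    out_n[[length(out_n) + 1L]] <-
      .rotate_naive(base$x_naive, angle, ds$naive_features)
  }
  ds2 <- base
  ds2$x_naive <- do.call(rbind, out_n)
  ds2$x_grid <- do.call(rbind, out_g)
  ds2$y <- rep(base$y, 4)
  ds2$driver_id <- rep(base$driver_id, 4)
  ds2$trip_id <- rep(base$trip_id, 4)
  ds2$start_index <- rep(base$start_index, 4)
  if (!is.null(ds2$has_episode)) ds2$has_episode <- rep(base$has_episode, 4)
  ds2
}

#' @export
print.dg_dataset <- function(x, ...) {
  cat("<dg_dataset>", length(x$y), "segments from",
      length(unique(x$driver_id)), "drivers\n",
      " window", x$window, "| cell", x$cell_km, "km | extent", x$extent,
      "| stride", x$stride, "| overflow dropped:", x$n_overflow, "\n")
  invisible(x)
}
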