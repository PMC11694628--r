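#' Slide a fixed time window across one trip
#'
#' Decomposes an n-record trip into windows of `w` consecutive records.
#' With a sliding step of one record the number of segments is
#' `n - w + 1` (zero when the window exceeds the trip).
#'
#' @param trip data.frame of time-ordered records from a single trip.
#' @param w window length in records (>= 2).
#' @param stride sliding step in records; 1 reproduces the canonical
#'   segmentation, larger values thin the (heavily overlapping) windows.
#' @return list of data.frames of `w` rows each, every element carrying a
#'   `start_index` attribute (1-based offset within the trip).
#' @export
segment_trajectory <- function(trip, w, stride = 1L) {
  if (w < 2) stop("window must be at least 2 records", call. = FALSE)
  stopifnot(stride >= 1)
  n <- nrow(trip)
  if (n < w) return(list())
  starts <- as.integer(seq.int(1L, n - w + 1L, by = stride))
  lapply(starts, function(s) {
    seg <- trip[s:(s + w - 1L), , drop = FALSE]
    attr(seg, "start_index") <- s
    seg
  })
}

#' Express a segment in km offsets from its starting fix
#'
#' Shift-to-origin: the first fix becomes the local origin and every fix
#' is re-expressed as east/north offsets in kilometres via an
#' equirectangular projection. The east-west scale is `cos(ref_lat)`;
#' holding `ref_lat` fixed across a dataset (the pipeline passes the
#' cohort origin) makes the local offsets — and hence the grid indices —
#' exactly invariant under translation of the segment, which is the
#' property the downstream classifier relies on. With `ref_lat = NULL`
#' the segment's own starting latitude is used.
#'
#' @param segment data.frame with `lat`, `lon` columns.
#' @param ref_lat reference latitude in degrees for the east-west metric
#'   scale, or `NULL` for the segment's starting latitude.
#' @param radius_km Earth radius in kilometres.
#' @return the segment with `x_km` (east) and `y_km` (north) columns
#'   appended; the first row is (0, 0).
#' @export
shift_to_origin <- function(segment, ref_lat = NULL,
                            radius_km = EARTH_RADIUS_KM) {
  stopifnot(nrow(segment) >= 1)
  lat0 <- segment$lat[1]
  lon0 <- segment$lon[1]
  if (is.null(ref_lat)) ref_lat <- lat0
  kscale <- radius_km * DEG2RAD
  segment$x_km <- (segment$lon - lon0) * kscale * cos(ref_lat * DEG2RAD)
  segment$y_km <- (segment$lat - lat0) * kscale
  segment
}

#' Assign integer grid indices to a local-coordinate segment
#'
#' Tiles the local plane into `cell_km` x `cell_km` cells and floors each
#' offset to its cell: `index = floor(offset / cell_km)` per axis, so the
#' starting fix always lands in cell (0, 0). `x` indexes the longitude
#' (east) axis and `y` the latitude (north) axis; indices west or south
#' of the start are negative.
#'
#' @param local_segment output of [shift_to_origin()].
#' @param cell_km cell edge length in kilometres (> 0).
#' @return data.frame with integer columns `ix`, `iy` and attribute
#'   `cell_km`.
#' @export
assign_grid_indices <- function(local_segment, cell_km = 1) {
  if (cell_km <= 0) stop("cell size must be positive", call. = FALSE)
  stopifnot(all(c("x_km", "y_km") %in% names(local_segment)))
  out <- data.frame(ix = as.integer(floor(local_segment$x_km / cell_km)),
                    iy = as.integer(floor(local_segment$y_km / cell_km)))
  attr(out, "cell_km") <- cell_km
  out
}

#' Re-anchor a grid-index sequence at the axis minima
#'
#' Translates indices so the minimum along each axis is 0. Used before
#' rasterization (paths may extend west/south of the start) and after
#' rotation.
#'
#' @param indices data.frame with `ix`, `iy`.
#' @return re-translated indices, attributes preserved.
#' @export
normalize_indices <- function(indices) {
  indices$ix <- indices$ix - min(indices$ix)
  indices$iy <- indices$iy - min(indices$iy)
  indices
}

#' Rotate a grid-index sequence by a quarter-turn multiple
#'
#' Counterclockwise rotation of the index lattice: 90 deg maps
#' (x, y) -> (-y, x), 180 deg -> (-x, -y), 270 deg -> (y, -x); the result
#' is re-anchored so the minimum index per axis is 0.
#'
#' @param indices data.frame with `ix`, `iy`.
#' @param angle rotation in degrees, one of 0, 90, 180, 270 (CCW).
#' @return rotated, re-anchored index sequence.
#' @export
rotate_indices <- function(indices, angle) {
  if (!angle %in% c(0, 90, 180, 270))
    stop("unsupported rotation angle: ", angle, call. = FALSE)
  x <- indices$ix; y <- indices$iy
  rot <- switch(as.character(angle),
                "0"   = list(x,  y),
                "90"  = list(-y, x),
                "180" = list(-x, -y),
                "270" = list(y,  -x))
  indices$ix <- as.integer(rot[[1]])
  indices$iy <- as.integer(rot[[2]])
  normalize_indices(indices)
}

#' Rasterize a grid-index sequence to a binary occupancy matrix
#'
#' Marks every visited cell with 1 on a `extent_g` x `extent_g` grid
#' after re-anchoring the sequence at the axis minima. Row 1 of the
#' matrix is the southernmost row (y = 0) and column 1 the westernmost
#' (x = 0). A segment whose bounding box exceeds the extent cannot be
#' represented and yields `NULL`; the dataset builder counts and drops
#' such segments rather than clipping them.
#'
#' @param indices data.frame with `ix`, `iy`.
#' @param extent_g cells per side (>= 1).
#' @return `extent_g` x `extent_g` 0/1 matrix, or `NULL` on overflow.
#' @export
rasterize_occupancy <- function(indices, extent_g = 3) {
  stopifnot(extent_g >= 1)
  idx <- normalize_indices(indices)
  if (max(idx$ix) >= extent_g || max(idx$iy) >= extent_g) return(NULL)
  m <- matrix(0L, nrow = extent_g, ncol = extent_g)
  m[cbind(idx$iy + 1L, idx$ix + 1L)] <- 1L
  m
}

#' Rotate an occupancy matrix by a quarter-turn multiple
#'
#' Counterclockwise rotation of the occupied cell set, re-anchored at the
#' matrix corner, so that rotating a sequence and then rasterizing equals
#' rasterizing and then rotating the matrix.
#'
#' @param mat 0/1 occupancy matrix (rows = y from south, cols = x from
#'   west).
#' @param angle one of 0, 90, 180, 270 degrees CCW.
#' @return rotated occupancy matrix of the same dimension.
#' @export
rotate_occupancy <- function(mat, angle) {
  occ <- which(mat == 1L, arr.ind = TRUE)
  if (nrow(occ) == 0L) return(mat)
  idx <- data.frame(ix = occ[, "col"] - 1L, iy = occ[, "row"] - 1L)
  out <- rasterize_occupancy(rotate_indices(idx, angle), nrow(mat))
  out
}

#' Rotation-augment a grid-index sequence
#'
#' Returns the identity and the three quarter-turn rotations of a
#' segment's index sequence, each re-anchored at the axis minima. Adding
#' the rotated copies to the training data teaches the classifier that a
#' manoeuvre is the same manoeuvre whatever the street orientation.
#'
#' @param indices data.frame with `ix`, `iy`.
#' @return named list of four index sequences
#'   (`rot0`, `rot90`, `rot180`, `rot270`).
#' @export
augment_segment <- function(indices) {
  list(rot0   = rotate_indices(indices, 0),
       rot90  = rotate_indices(indices, 90),
       rot180 = rotate_indices(indices, 180),
       rot270 = rotate_indices(indices, 270))
}
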