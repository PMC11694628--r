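test_that("sliding-window segment count obeys n - w + 1", {
  trip <- make_east_trip(13)
  segs <- segment_trajectory(trip, 13)
  expect_length(segs, 1)
  expect_equal(nrow(segs[[1]]), 13)
  expect_length(segment_trajectory(make_east_trip(20), 13), 8)
  expect_length(segment_trajectory(make_east_trip(5), 13), 0)
  expect_error(segment_trajectory(trip, 1), "window")
  # exhaustive law over the full small-instance grid
  for (n in 2:50) {
    trip_n <- make_east_trip(n)
    for (w in 2:20) {
      expect_length(segment_trajectory(trip_n, w), max(n - w + 1, 0))
    }
  }
  # windows are contiguous, stride 1, and record their start offset
  segs <- segment_trajectory(make_east_trip(20), 5)
  expect_equal(vapply(segs, attr, 1L, "start_index"), 1:16)
  expect_equal(segs[[3]]$timestamp, 3:7)
})

test_that("shift-to-origin zeroes the start and preserves constructed geometry", {
  seg <- make_east_trip(10, lat = 0, step_deg = 1e-3)
  loc <- shift_to_origin(seg)
  expect_equal(loc$x_km[1], 0)
  expect_equal(loc$y_km[1], 0)
  expect_true(all(diff(loc$x_km) > 0))
  expect_equal(loc$y_km, rep(0, 10))
  # eastward degrees convert at the cos(lat)-scaled arc length
  expect_equal(loc$x_km[2], 1e-3 * pi / 180 * 6371, tolerance = 1e-9)
})

test_that("translation invariance: translated segments yield identical grid indices", {
  # the pipeline holds the east-west reference latitude fixed per
  # dataset, under which shift-to-origin is exactly translation
  # invariant (Lemma 1)
  set.seed(99)
  ref <- 40
  for (i in 1:1000) {
    seg <- random_segment(n = 13, lat0 = 40 + runif(1, -1, 1),
                          lon0 = -75 + runif(1, -1, 1))
    dlat <- runif(1, -0.1, 0.1)
    dlon <- runif(1, -0.1, 0.1)
    moved <- seg
    moved$lat <- seg$lat + dlat
    moved$lon <- seg$lon + dlon
    i1 <- assign_grid_indices(shift_to_origin(seg, ref_lat = ref), 0.1)
    i2 <- assign_grid_indices(shift_to_origin(moved, ref_lat = ref), 0.1)
    expect_identical(i1$ix, i2$ix)
    expect_identical(i1$iy, i2$iy)
  }
})

test_that("grid indices floor offsets into cells with the start at (0,0)", {
  loc <- data.frame(x_km = c(0, 0.4, 0.9), y_km = c(0, 0.2, 0.8))
  idx <- assign_grid_indices(loc, 1)
  expect_equal(idx$ix, c(0L, 0L, 0L))
  expect_equal(idx$iy, c(0L, 0L, 0L))
  # eastward path 2.5 cells long crosses x cells 0,1,2
  loc2 <- data.frame(x_km = seq(0, 2.5, by = 0.25), y_km = 0)
  idx2 <- assign_grid_indices(loc2, 1)
  expect_equal(sort(unique(idx2$ix)), c(0L, 1L, 2L))
  expect_true(all(idx2$iy == 0L))
  # offsets west/south of the start go negative
  loc3 <- data.frame(x_km = c(0, -0.1), y_km = c(0, -1.2))
  idx3 <- assign_grid_indices(loc3, 1)
  expect_equal(idx3$ix, c(0L, -1L))
  expect_equal(idx3$iy, c(0L, -2L))
  expect_error(assign_grid_indices(loc, 0), "cell size")
})

test_that("worked-example path rasterizes to the expected 3x3 occupancy", {
  idx <- worked_example_indices()
  expect_equal(max(idx$ix), 2L)
  expect_equal(max(idx$iy), 2L)
  m <- rasterize_occupancy(idx, 3)
  # rows are y from the south, columns x from the west
  expected <- matrix(0L, 3, 3)
  for (cell in list(c(0, 0), c(1, 0), c(2, 0), c(2, 1), c(1, 1),
                    c(1, 2), c(0, 2)))
    expected[cell[2] + 1, cell[1] + 1] <- 1L
  expect_identical(m, expected)
  expect_equal(m[2, 1], 0L)  # cell (0,1) never visited
  expect_equal(m[3, 3], 0L)  # cell (2,2) never visited
  expect_equal(sum(m), 7)    # entry sum = number of distinct visited cells
})

test_that("rasterization marks exactly the distinct visited cells", {
  # single-cell path
  one <- rasterize_occupancy(data.frame(ix = c(0L, 0L), iy = c(0L, 0L)), 3)
  expect_equal(sum(one), 1)
  # random paths: entry sum equals distinct cell count (set oracle)
  set.seed(7)
  for (i in 1:50) {
    idx <- data.frame(ix = sample(0:4, 20, TRUE), iy = sample(0:4, 20, TRUE))
    m <- rasterize_occupancy(idx, 5)
    idx_n <- normalize_indices(idx)
    expect_equal(sum(m), nrow(unique(idx_n)))
    expect_true(all(m %in% c(0L, 1L)))
  }
  # overflow contract: too-large bounding box yields NULL, not clipping
  wide <- data.frame(ix = c(0L, 5L), iy = c(0L, 0L))
  expect_null(rasterize_occupancy(wide, 3))
})

test_that("quarter-turn rotations compose to the identity and hit known images", {
  path <- data.frame(ix = c(0L, 1L), iy = c(0L, 0L))
  r180 <- rotate_indices(path, 180)
  expect_equal(r180$ix, c(1L, 0L))
  expect_equal(r180$iy, c(0L, 0L))
  # four 90-degree turns return every tested sequence to itself
  set.seed(3)
  for (i in 1:100) {
    idx <- data.frame(ix = sample(-3:3, 10, TRUE), iy = sample(-3:3, 10, TRUE))
    four <- rotate_indices(rotate_indices(rotate_indices(
      rotate_indices(idx, 90), 90), 90), 90)
    expect_identical(four, normalize_indices(idx))
  }
  expect_error(rotate_indices(path, 45), "unsupported")
})

test_that("rotation and rasterization commute, preserving cell counts", {
  # brute-force cell-set oracle: rotating the set of occupied cells
  # directly must agree with rotating the matrix
  set.seed(5)
  for (G in 3:5) {
    for (i in 1:40) {
      idx <- data.frame(ix = sample(0:(G - 1), 8, TRUE),
                        iy = sample(0:(G - 1), 8, TRUE))
      for (angle in c(90, 180, 270)) {
        a <- rasterize_occupancy(rotate_indices(idx, angle), G)
        b <- rotate_occupancy(rasterize_occupancy(idx, G), angle)
        expect_identical(a, b)
        expect_equal(sum(a), nrow(unique(normalize_indices(idx))))
      }
    }
  }
})

test_that("augmentation yields four labeled variants and quadruples datasets", {
  idx <- data.frame(ix = c(0L, 1L, 1L), iy = c(0L, 0L, 1L))  # L-shape
  aug <- augment_segment(idx)
  expect_length(aug, 4)
  expect_named(aug, c("rot0", "rot90", "rot180", "rot270"))
  # occupied-cell multiset cardinality is rotation invariant
  counts <- vapply(aug, function(s) nrow(unique(s)), integer(1))
  expect_true(all(counts == 3L))
  # a symmetric single-cell path is a fixed point of all rotations
  pt <- data.frame(ix = 0L, iy = 0L)
  augpt <- augment_segment(pt)
  for (s in augpt) expect_identical(s, pt)
})
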