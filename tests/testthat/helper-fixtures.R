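# Small trajectory fixtures built in code.

# Constant-velocity trip heading due east at the equator-adjacent
# latitude `lat`; `step_deg` degrees of longitude per second.
make_east_trip <- function(n = 13, lat = 10, lon0 = 20, step_deg = 1e-4) {
  data.frame(timestamp = seq_len(n), lat = lat,
             lon = lon0 + (seq_len(n) - 1) * step_deg)
}

make_stationary_trip <- function(n = 5, lat = 10, lon = 20) {
  data.frame(timestamp = seq_len(n), lat = lat, lon = lon)
}

# The worked 13-point example path: along the bottom row east, up and
# back west through the middle, then up to the top row — visiting the
# cells (0,0),(1,0),(2,0),(2,1),(1,1),(1,2),(0,2) of a 3x3 grid.
worked_example_indices <- function() {
  data.frame(ix = c(0L, 0L, 1L, 1L, 2L, 2L, 2L, 1L, 1L, 1L, 1L, 0L, 0L),
             iy = c(0L, 0L, 0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L, 2L, 2L, 2L))
}

# Random short city-scale segment: a lat/lon random walk of `n` fixes
# starting at (lat0, lon0), steps of a few metres to tens of metres.
random_segment <- function(n = 13, lat0 = 40, lon0 = -75,
                           step_sd_deg = 3e-4) {
  lat <- lat0 + cumsum(c(0, stats::rnorm(n - 1, sd = step_sd_deg)))
  lon <- lon0 + cumsum(c(0, stats::rnorm(n - 1, sd = step_sd_deg)))
  data.frame(timestamp = seq_len(n), lat = lat, lon = lon)
}

# Tiny linearly separable two-class tabular set.
make_separable <- function(n_per_class = 60, p = 5, gap = 3, seed = 7) {
  set.seed(seed)
  x0 <- matrix(stats::rnorm(n_per_class * p), n_per_class, p)
  x1 <- matrix(stats::rnorm(n_per_class * p, mean = gap), n_per_class, p)
  list(x_naive = rbind(x0, x1),
       y = rep(c(0L, 1L), each = n_per_class))
}
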