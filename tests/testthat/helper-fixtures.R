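# shared fixtures for the test suite; everything is built in code

# detections of one constant box over given slices
const_box_dets <- function(slices, box = c(10, 10, 20, 20),
                           confidence = 0.9) {
  detections(slices,
             matrix(rep(box, length(slices)), ncol = 4, byrow = TRUE),
             confidence)
}

# a track holding the same box on every slice of [z1, z2]
const_track <- function(id, z1, z2, box) {
  n <- z2 - z1 + 1
  spine_track(id, z1, z2, matrix(rep(box, n), ncol = 4, byrow = TRUE))
}

# random valid boxes, coordinates on a grid of `snap` px (0 = continuous)
random_boxes <- function(n, max_coord = 30, min_size = 2, max_size = 15,
                         snap = 0) {
  x0 <- runif(n, 0, max_coord - max_size)
  y0 <- runif(n, 0, max_coord - max_size)
  w <- runif(n, min_size, max_size)
  h <- runif(n, min_size, max_size)
  m <- cbind(x_min = x0, y_min = y0, x_max = x0 + w, y_max = y0 + h)
  if (snap > 0) m <- round(m / snap) * snap
  m
}

# counting oracle for box overlap scores: rasterize both boxes on a grid
# of `cell` px (cell centres at odd multiples of cell/2) and count cells.
# Independent of the closed-form area arithmetic in the package.
raster_overlap_oracle <- function(b1, b2, cell = 0.01) {
  count_1d <- function(lo, hi) {
    i0 <- ceiling(lo / cell - 0.5)
    i1 <- floor(hi / cell - 0.5 + 1e-12)
    centers_lo <- (i0 + 0.5) * cell
    if (centers_lo < lo) i0 <- i0 + 1
    max(0, i1 - i0 + 1)
  }
  cells_in_box <- function(b) {
    count_1d(b[1], b[3]) * count_1d(b[2], b[4])
  }
  n1 <- cells_in_box(b1)
  n2 <- cells_in_box(b2)
  lo_x <- max(b1[1], b2[1]); hi_x <- min(b1[3], b2[3])
  lo_y <- max(b1[2], b2[2]); hi_y <- min(b1[4], b2[4])
  ni <- if (hi_x > lo_x && hi_y > lo_y) {
    count_1d(lo_x, hi_x) * count_1d(lo_y, hi_y)
  } else 0
  list(iou = if (n1 + n2 - ni > 0) ni / (n1 + n2 - ni) else 0,
       iom = if (min(n1, n2) > 0) ni / min(n1, n2) else 0)
}

# small, quick simulation settings used by unit tests (the full-size
# defaults are exercised by the acceptance suite)
small_sim_params <- function(seed, n_spines = 6, ...) {
  simulation_params(image_size = 192, n_slices = 10, n_dendrites = 1,
                    n_spines = n_spines, seed = seed, ...)
}
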