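test_that("simulation is deterministic under a fixed seed", {
  p <- small_sim_params(seed = 4)
  a <- simulate_stack(p)
  b <- simulate_stack(p)
  expect_identical(a$stack$slices, b$stack$slices)
  expect_identical(tracks_to_df(a$ground_truth),
                   tracks_to_df(b$ground_truth))
})

test_that("a spineless simulation yields dendrites only and empty ground truth", {
  res <- simulate_stack(small_sim_params(seed = 5, n_spines = 0))
  expect_length(res$ground_truth, 0)
  expect_equal(n_slices(res$stack), 10)
  # the dendrite is bright somewhere
  expect_gt(max(res$stack$slices[[1]]), 200)
})

test_that("ground-truth geometry respects the configured bounds", {
  for (seed in 1:4) {
    sim <- simulate_ground_truth(small_sim_params(seed = seed))
    expect_length(sim$tracks, 6)
    df <- tracks_to_df(sim$tracks)
    expect_true(all(df$x_min >= 0 & df$y_min >= 0))
    expect_true(all(df$x_max <= sim$image_size))
    expect_true(all(df$y_max <= sim$image_size))
    expect_true(all(df$slice >= 0 & df$slice < sim$n_slices))
    expect_true(all(box_area(df) <= 1300))
    # non-overlapping placements: distinct spines never overlap in-plane
    for (s in unique(df$slice)) {
      b <- df[df$slice == s, ]
      if (nrow(b) > 1) {
        for (i in 1:(nrow(b) - 1)) for (j in (i + 1):nrow(b)) {
          expect_equal(intersection_area(as.numeric(b[i, 3:6]),
                                         as.numeric(b[j, 3:6])), 0)
        }
      }
    }
  }
})

test_that("rendered spine components match their target box areas on the central slice", {
  p <- simulation_params(image_size = 256, n_slices = 9, n_dendrites = 1,
                         n_spines = 10, background_noise_sd = 0,
                         background_level = 0, seed = 17)
  res <- simulate_stack(p)
  expect_length(res$ground_truth, 10)
  sim <- res$simulation
  dend_layer <- spinetrack:::render_dendrite_layer(sim)
  for (k in seq_along(sim$spines)) {
    sp <- sim$spines[[k]]
    gt <- res$ground_truth[[k]]
    target <- box_area(gt$boxes[which.max(
      spinetrack:::spine_z_profile(sp$z1, sp$z2)), ])
    # measure the rendered component on its central slice: pixels above
    # the ellipse-boundary intensity, inside the ground-truth window
    mid <- sp$z1 + which.max(spinetrack:::spine_z_profile(sp$z1, sp$z2)) - 1
    img <- res$stack$slices[[mid + 1]]
    bb <- gt$boxes[mid - gt$z_first + 1, ]
    r0 <- max(1, floor(bb[2]) - 2); r1 <- min(nrow(img), ceiling(bb[4]) + 2)
    c0 <- max(1, floor(bb[1]) - 2); c1 <- min(ncol(img), ceiling(bb[3]) + 2)
    win <- img[r0:r1, c0:c1]
    # spine pixels above the ellipse-boundary intensity, excluding pixels
    # dominated by the dendritic shaft (the ground truth excludes them)
    dend_win <- dend_layer[r0:r1, c0:c1]
    mask <- win > sp$amp * exp(-2) & win > dend_win + 0.6
    px <- which(mask, arr.ind = TRUE)
    measured <- (diff(range(px[, 2])) + 1) * (diff(range(px[, 1])) + 1)
    expect_lt(abs(measured - target) / target, 0.2)
  }
})

test_that("zero-noise perturbation reproduces the ground truth boxes", {
  sim <- simulate_ground_truth(small_sim_params(seed = 6))
  ann <- perturb_annotations(
    sim, perturbation_params(corner_jitter_sd = 0, drop_prob = 0,
                             spurious_rate = 0))
  want <- tracks_to_detections(sim$tracks)
  got <- ann$boxes[order(ann$boxes$slice, ann$boxes$x_min), ]
  want <- want[order(want$slice, want$x_min), ]
  expect_equal(got$x_min, want$x_min)
  expect_equal(got$y_max, want$y_max)
  expect_equal(nrow(got), nrow(want))
})

test_that("the drop rate obeys binomial bounds over many spines", {
  # 40 spines x 5 panels = 200 Bernoulli trials at p = 0.5
  kept <- 0L
  total <- 0L
  for (seed in 1:5) {
    sim <- simulate_ground_truth(
      simulation_params(image_size = 400, n_slices = 8, n_dendrites = 2,
                        n_spines = 40, seed = 4000 + seed))
    ann <- perturb_annotations(
      sim, perturbation_params(corner_jitter_sd = 0, drop_prob = 0.5,
                               spurious_rate = 0, seed = 8000 + seed))
    tr <- build_annotator_tracks(ann, depth = sim$n_slices)
    kept <- kept + length(tr)
    total <- total + length(sim$tracks)
  }
  # binomial 99% bounds around p = 0.5 for n = 200: +- 2.58*sqrt(n)/2
  expect_gt(kept, 100 - 2.58 * sqrt(200) / 2 - 1)
  expect_lt(kept, 100 + 2.58 * sqrt(200) / 2 + 1)
})

test_that("corner jitter has the folded-normal mean displacement", {
  sim <- simulate_ground_truth(
    simulation_params(image_size = 400, n_slices = 20, n_dendrites = 2,
                      n_spines = 30, seed = 50))
  ann <- perturb_annotations(
    sim, perturbation_params(corner_jitter_sd = 1, drop_prob = 0,
                             spurious_rate = 0, seed = 51))
  want <- tracks_to_detections(sim$tracks)
  got <- ann$boxes
  # pair each true box with the jittered box of nearest centre on its slice
  pair <- vapply(seq_len(nrow(want)), function(i) {
    cand <- which(got$slice == want$slice[i])
    d2 <- (got$x_min[cand] + got$x_max[cand] -
             want$x_min[i] - want$x_max[i])^2 +
      (got$y_min[cand] + got$y_max[cand] -
         want$y_min[i] - want$y_max[i])^2
    cand[which.min(d2)]
  }, integer(1))
  expect_equal(sort(pair), seq_len(nrow(got)))  # a perfect matching
  disp <- abs(as.matrix(got[pair, c("x_min", "y_min", "x_max", "y_max")]) -
                as.matrix(want[c("x_min", "y_min", "x_max", "y_max")]))
  # E|N(0,1)| = sqrt(2/pi) ~ 0.798; allow generous sampling error
  expect_lt(abs(mean(disp) - sqrt(2 / pi)), 0.1)
})

test_that("annotator panels are independent but share the ground truth", {
  sim <- simulate_ground_truth(small_sim_params(seed = 61))
  panel <- make_annotator_panel(
    sim, 5, perturbation_params(corner_jitter_sd = 0, drop_prob = 0,
                                spurious_rate = 0))
  expect_length(panel, 5)
  for (i in 2:5) expect_equal(panel[[i]]$boxes, panel[[1]]$boxes)
  expect_equal(panel[[3]]$annotator_id, "annotator_3")
  single <- make_annotator_panel(sim, 1)
  expect_length(single, 1)
  # with seeded jitter, different annotators get different noise
  noisy <- make_annotator_panel(
    sim, 2, perturbation_params(corner_jitter_sd = 2, seed = 70))
  expect_false(isTRUE(all.equal(noisy[[1]]$boxes, noisy[[2]]$boxes)))
})

test_that("impossible spine packing raises an infeasible-geometry error", {
  expect_error(
    simulate_ground_truth(
      simulation_params(image_size = 64, n_slices = 6, n_dendrites = 1,
                        n_spines = 60, seed = 1)),
    "infeasible geometry")
})
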