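test_that("z-axis IoM handles overlap, identity and disjoint intervals", {
  expect_equal(iom_z(c(3, 7), c(5, 10)), 0.6)   # shared {5,6,7} / len 5
  expect_equal(iom_z(c(4, 4), c(4, 4)), 1)
  expect_equal(iom_z(c(0, 2), c(5, 9)), 0)
  expect_equal(iom_z(c(0, 9), c(3, 5)), 1)      # containment saturates
  expect_error(iom_z(c(5, 3), c(0, 1)), "z2 >= z1")
})

test_that("slice-count z IoM equals a brute-force count over slice sets", {
  set.seed(11)
  for (i in 1:100) {
    d <- sort(sample(0:20, 2, replace = TRUE))
    g <- sort(sample(0:20, 2, replace = TRUE))
    shared <- length(intersect(d[1]:d[2], g[1]:g[2]))
    denom <- min(length(d[1]:d[2]), length(g[1]:g[2]))
    expect_equal(iom_z(d, g), shared / denom)
  }
})

test_that("literal z convention reproduces the raw-difference formula and its degenerate cases", {
  expect_equal(iom_z(c(3, 7), c(5, 10), convention = "literal"), 2 / 4)
  expect_equal(iom_z(c(4, 4), c(4, 4), convention = "literal"), 1)
  expect_equal(iom_z(c(4, 4), c(4, 9), convention = "literal"), 0)
  expect_equal(iom_z(c(3, 3), c(4, 4), convention = "literal"), 0)
})

test_that("mean box averages coordinates over the covered slices", {
  tr <- spine_track(1, 0, 1, rbind(c(0, 0, 10, 10), c(2, 2, 12, 12)))
  expect_equal(unname(mean_box(tr)), c(1, 1, 11, 11))
  single <- spine_track(2, 3, 3, matrix(c(5, 6, 9, 12), nrow = 1))
  expect_equal(unname(mean_box(single)), c(5, 6, 9, 12))
  three <- const_track(3, 0, 2, c(4, 4, 8, 8))
  expect_equal(unname(mean_box(three)), c(4, 4, 8, 8))
})

test_that("combined 3D IoM is the F0.5 combination of its parts", {
  a <- const_track(1, 0, 4, c(0, 0, 10, 10))
  expect_equal(iom_3d(a, a), 1)
  # no z overlap forces 0
  b <- const_track(2, 10, 12, c(0, 0, 10, 10))
  expect_equal(iom_3d(a, b), 0)
  # x = 0.8, y = 0.5 -> 5xy/(x+4y) = 2/2.8
  d <- const_track(3, 0, 9, c(0, 0, 10, 10))     # z len 10
  e <- const_track(4, 5, 14, c(2, 0, 12, 10))    # shares 5 of 10 slices
  expect_equal(iom_xy_2d(mean_box(d), mean_box(e)), 0.8)
  expect_equal(iom_z(d, e), 0.5)
  expect_equal(iom_3d(d, e), 2 / 2.8)
  expect_equal(iom_3d(d, e), iom_3d(e, d))       # symmetric
})

test_that("F1 follows 2TP/(2TP+FP+FN) and warns on the empty case", {
  expect_equal(f1_score(2, 0, 0), 1)
  expect_equal(f1_score(8, 2, 2), 0.8)
  expect_equal(f1_score(0, 1, 1), 0)
  expect_equal(f1_score(3, 1, 2), f1_score(3, 2, 1))  # fp/fn symmetric
  expect_warning(z <- f1_score(0, 0, 0), "undefined")
  expect_equal(z, 0)
})

test_that("3D matching counts TP/FP/FN under both matching modes", {
  gt <- const_track(1, 0, 4, c(0, 0, 10, 10))
  det_good <- const_track(1, 1, 4, c(1, 0, 11, 10))
  r <- match_3d(list(det_good), list(gt), threshold = 0.5)
  expect_equal(c(r$tp, r$fp, r$fn), c(1, 0, 0))
  expect_equal(r$f1, 1)

  r_empty <- match_3d(list(), list(gt, gt, gt), threshold = 0.5)
  expect_equal(c(r_empty$tp, r_empty$fp, r_empty$fn), c(0, 0, 3))

  # a score of exactly the threshold counts as a match
  half <- const_track(1, 0, 4, c(5, 0, 15, 10))  # x = 0.5, y = 1
  expect_equal(iom_3d(half, gt), 5 * 0.5 / (0.5 + 4))
  thr <- iom_3d(half, gt)
  r_eq <- match_3d(list(half), list(gt), threshold = thr)
  expect_equal(r_eq$tp, 1)

  # existential mode scores duplicate detections of one spine as two TPs
  r_dup <- match_3d(list(det_good, det_good), list(gt))
  expect_equal(c(r_dup$tp, r_dup$fp, r_dup$fn), c(2, 0, 0))
  # one-to-one mode pairs each side at most once
  r_121 <- match_3d(list(det_good, det_good), list(gt), mode = "one_to_one")
  expect_equal(c(r_121$tp, r_121$fp, r_121$fn), c(1, 1, 0))
})

test_that("matching invariants hold on random track sets", {
  set.seed(7)
  for (rep in 1:20) {
    dets <- lapply(seq_len(sample(0:6, 1)), function(i) {
      z1 <- sample(0:8, 1)
      const_track(i, z1, z1 + sample(0:4, 1), random_boxes(1))
    })
    gts <- lapply(seq_len(sample(1:6, 1)), function(i) {
      z1 <- sample(0:8, 1)
      const_track(i, z1, z1 + sample(0:4, 1), random_boxes(1))
    })
    re <- match_3d(dets, gts, mode = "existential")
    expect_equal(re$tp + re$fp, length(dets))
    r1 <- match_3d(dets, gts, mode = "one_to_one")
    expect_lte(r1$tp, min(length(dets), length(gts)))
    expect_equal(r1$tp + r1$fp, length(dets))
    expect_equal(r1$tp + r1$fn, length(gts))
  }
})

test_that("2D evaluation matches per slice and aggregates counts", {
  gt <- data.frame(slice = c(3L, 3L, 4L),
                   x_min = c(0, 20, 0), y_min = c(0, 0, 0),
                   x_max = c(10, 30, 10), y_max = c(10, 10, 10))
  # identical detections -> perfect
  d_same <- detections(gt$slice, gt[2:5], 0.9)
  expect_equal(evaluate_2d(d_same, gt)$f1, 1)
  # right boxes on the wrong slice -> zero
  d_wrong <- detections(gt$slice + 10L, gt[2:5], 0.9)
  expect_equal(evaluate_2d(d_wrong, gt)$f1, 0)
  # partial: 2 of 3 matched plus one spurious -> f1 = 4/7... computed via counts
  d_part <- detections(c(3L, 3L, 3L),
                       rbind(c(0, 0, 10, 10), c(20, 0, 30, 10),
                             c(100, 100, 120, 120)), 0.9)
  r <- evaluate_2d(d_part, gt)
  expect_equal(c(r$tp, r$fp, r$fn), c(2, 1, 1))
  expect_equal(r$f1, f1_score(2, 1, 1))
})

test_that("match reports serialise to JSON with counts and pairs", {
  gt <- const_track(1, 0, 4, c(0, 0, 10, 10))
  r <- match_3d(list(gt), list(gt))
  path <- withr::local_tempfile(fileext = ".json")
  write_match_report(r, path, config = pipeline_config())
  back <- jsonlite::fromJSON(path)
  expect_equal(back$tp, 1)
  expect_equal(back$f1, 1)
  expect_equal(back$config$beta, 0.5)
})
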