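test_that("anchor grids match the closed-form count and geometry", {
  # one 64-px stride on a 64x64 image: a single centre, three ratios
  cfg1 <- anchor_config(strides = 64, image_size = 64)
  a1 <- generate_anchors(cfg1)
  expect_equal(nrow(a1), 3)
  expect_equal(nrow(a1), anchor_count(cfg1))

  # ratio 1, scale 8, stride 4 anchors are 32x32 squares
  cfg_sq <- anchor_config(strides = 4, aspect_ratios = 1, image_size = 16)
  sq <- generate_anchors(cfg_sq)
  expect_true(all(abs((sq[, 3] - sq[, 1]) - 32) < 1e-12))
  expect_true(all(abs((sq[, 4] - sq[, 2]) - 32) < 1e-12))
  # centres sit on the half-stride grid
  expect_equal(sort(unique((sq[, 1] + sq[, 3]) / 2)), c(2, 6, 10, 14))

  # default full-size configuration: 3 * (128^2+64^2+32^2+16^2+8^2)
  cfg <- anchor_config()
  expect_equal(anchor_count(cfg), 65472)
  expect_equal(nrow(generate_anchors(cfg)), 65472)

  # property: enumeration equals the closed form for random configs
  set.seed(12)
  for (i in 1:25) {
    cfg_r <- anchor_config(
      scales = sample(1:8, sample(1:2, 1)),
      strides = sample(c(2, 4, 8, 16, 32), sample(1:3, 1)),
      aspect_ratios = runif(sample(1:4, 1), 0.25, 4),
      image_size = sample(16:96, 2))
    W <- cfg_r$image_size[1]
    H <- cfg_r$image_size[2]
    n_direct <- length(cfg_r$aspect_ratios) * length(cfg_r$scales) *
      sum(floor(W / cfg_r$strides) * floor(H / cfg_r$strides))
    expect_equal(nrow(generate_anchors(cfg_r)), n_direct)
    expect_equal(anchor_count(cfg_r), n_direct)
  }
})

test_that("anchor labels follow the argmax-and-threshold rule", {
  gts <- rbind(c(10, 10, 42, 42))
  anchors <- rbind(
    c(10, 10, 42, 42),     # identical to the gt -> positive
    c(11, 11, 43, 43),     # high IoU but not argmax -> ignore
    c(200, 200, 232, 232), # no overlap -> negative
    c(20, 20, 52, 52))     # moderate IoU -> ignore
  lab <- assign_anchor_labels(anchors, gts)
  expect_equal(lab, c("positive", "ignore", "negative", "ignore"))

  # the strict rule withholds the positive label when argmax IoU < 0.7
  weak_gt <- rbind(c(100, 100, 110, 110))
  weak_anchor <- rbind(c(104, 100, 114, 110))  # IoU 6/14
  expect_equal(assign_anchor_labels(weak_anchor, weak_gt), "ignore")
  expect_equal(assign_anchor_labels(weak_anchor, weak_gt,
                                    rule = "standard"), "positive")

  # no ground truth: everything negative
  expect_equal(assign_anchor_labels(anchors, NULL), rep("negative", 4))

  # every gt with argmax IoU >= 0.7 has a positive anchor; none both ways
  set.seed(8)
  for (i in 1:10) {
    A <- random_boxes(30, max_coord = 60)
    G <- random_boxes(4, max_coord = 60)
    lab <- assign_anchor_labels(A, G)
    S <- sapply(seq_len(nrow(G)), function(j)
      sapply(seq_len(nrow(A)), function(i) iou_2d(A[i, ], G[j, ])))
    for (j in seq_len(nrow(G))) {
      if (max(S[, j]) >= 0.7) {
        expect_equal(lab[which.max(S[, j])], "positive")
      }
    }
    expect_true(all(lab[apply(S, 1, max) < 0.3 &
                          lab != "positive"] == "negative"))
  }
})

test_that("the eight orientations are distinct, closed and area-preserving", {
  set.seed(2)
  img <- matrix(runif(12 * 12), 12, 12)
  or8 <- enumerate_orientations(img)
  expect_length(or8, 8)
  # pairwise distinct for a generic image
  for (i in 1:7) for (j in (i + 1):8) {
    expect_false(isTRUE(all.equal(or8[[i]], or8[[j]])))
  }
  # constant image: all eight outputs equal
  or_const <- enumerate_orientations(matrix(1, 5, 5))
  for (o in or_const) expect_equal(o, matrix(1, 5, 5))
  # closure: re-orienting any of the 8 yields arrays inside the original 8
  canon <- vapply(or8, function(m) paste(round(m, 10), collapse = ","), "")
  for (o in or8) {
    again <- enumerate_orientations(o)
    for (m in again) {
      expect_true(paste(round(m, 10), collapse = ",") %in% canon)
    }
  }
  # non-square shapes transpose under odd rotations
  rect <- matrix(runif(6), 2, 3)
  expect_equal(dim(enumerate_orientations(rect)$rot90), c(3, 2))
})

test_that("augmentation is seed-reproducible and orientation-consistent for boxes", {
  set.seed(77)
  img <- matrix(runif(40 * 60, 0, 255), 40, 60)
  boxes <- rbind(c(10, 20, 30, 35), c(2, 2, 8, 9))
  set.seed(123)
  a1 <- augment(img, boxes)
  set.seed(123)
  a2 <- augment(img, boxes)
  expect_identical(a1, a2)
  # orientations preserve box areas exactly
  for (o in 1:50) {
    set.seed(o)
    a <- augment(img, boxes, p_noise = 0, p_blur = 0)
    expect_equal(box_area(a$boxes), box_area(boxes))
    expect_true(all(a$boxes >= 0))
    # boxes stay inside the (possibly transposed) image frame
    expect_true(all(a$boxes[, 3] <= max(dim(img))))
  }
  # output range clipped to [0, 255]
  set.seed(9)
  noisy <- augment(img, noise_sd = 50, p_noise = 1, p_blur = 0)
  expect_true(all(noisy$image >= 0 & noisy$image <= 255))
})

test_that("the combined loss weights regression and regularisation as documented", {
  expect_equal(combine_losses(0, 0, 0, 0, 0), 0)
  expect_equal(combine_losses(1, 0.5, 0, 0, 0), 2)
  expect_equal(combine_losses(0, 0, 0, 0, 1e6), 3)
  expect_equal(combine_losses(1, 1, 1, 1, 0), 6)
  # linear in each argument
  base <- combine_losses(1, 2, 3, 4, 5)
  expect_equal(combine_losses(2, 2, 3, 4, 5) - base, 1)
  expect_equal(combine_losses(1, 3, 3, 4, 5) - base, 2)
  expect_equal(combine_losses(1, 2, 3, 4, 6) - base, 3e-6)
  expect_error(combine_losses(-1, 0, 0, 0, 0))
  # constants carried by the training recipe
  tc <- training_constants()
  expect_equal(tc$alpha, 2)
  expect_equal(tc$lambda, 3e-6)
  expect_equal(tc$n_rpn, 1000L)
  expect_equal(tc$n_boxc, 80L)
})

test_that("the reference detector finds isolated blobs and ignores blank images", {
  blank <- matrix(10, 64, 64)
  expect_equal(nrow(reference_detect(blank)), 0)

  blob_img <- function(centres, amp = 200, size = 96) {
    img <- matrix(5, size, size)
    for (ct in centres) {
      for (r in seq_len(size)) {
        img[r, ] <- pmax(img[r, ], amp * exp(-(((seq_len(size) - 0.5) -
          ct[1])^2 + ((r - 0.5) - ct[2])^2) / (2 * 3^2)))
      }
    }
    img
  }
  one <- reference_detect(blob_img(list(c(30, 40))))
  expect_equal(nrow(one), 1)
  expect_true(one$x_min < 30 & 30 < one$x_max)
  expect_true(one$y_min < 40 & 40 < one$y_max)
  expect_true(one$confidence > 0.5 && one$confidence <= 1)

  two <- reference_detect(blob_img(list(c(25, 25), c(70, 65))))
  expect_equal(nrow(two), 2)
})

test_that("the detector registry resolves named detectors", {
  expect_true("reference" %in% list_detectors())
  expect_error(get_detector("no_such"), "unknown detector")
  register_detector("null_detector", function(image, slice = 0L, ...) {
    spinetrack:::empty_detections()
  })
  stack <- image_stack(list(matrix(0, 32, 32), matrix(0, 32, 32)))
  expect_equal(nrow(detect_stack(stack, "null_detector")), 0)
})
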