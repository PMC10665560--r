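ann_from_boxes <- function(slices, box, id = "a") {
  annotation_set(
    data.frame(slice = slices,
               x_min = box[1], y_min = box[2],
               x_max = box[3], y_max = box[4]),
    annotator_id = id)
}

test_that("annotator labels are tracked with the same two-miss rule", {
  # one box across slices 2-6 -> one track
  a <- ann_from_boxes(2:6, c(10, 10, 20, 20))
  tr <- build_annotator_tracks(a)
  expect_length(tr, 1)
  expect_equal(c(tr[[1]]$z_first, tr[[1]]$z_second), c(2, 6))

  # two disjoint boxes per slice -> two tracks
  b <- annotation_set(rbind(
    data.frame(slice = 0:2, x_min = 0, y_min = 0, x_max = 10, y_max = 10),
    data.frame(slice = 0:2, x_min = 50, y_min = 50, x_max = 60,
               y_max = 60)))
  expect_length(build_annotator_tracks(b), 2)

  # a two-slice hole splits the label into two tracks
  c_ <- ann_from_boxes(c(0:2, 5:7), c(10, 10, 20, 20))
  expect_length(build_annotator_tracks(c_, depth = 8), 2)
})

test_that("clustering counts distinct supporting annotators", {
  mk_panel <- function(ids, box = c(10, 10, 20, 20)) {
    setNames(lapply(ids, function(i)
      build_annotator_tracks(ann_from_boxes(1:5, box, id = i))), ids)
  }
  # five identical annotators -> one cluster with support 5
  cl <- cluster_annotations(mk_panel(paste0("a", 1:5)))
  expect_length(cl, 1)
  expect_equal(cl[[1]]$support, 5)

  # three coincident tracks, two annotators with nothing there -> support 3
  panel <- c(mk_panel(paste0("a", 1:3)),
             setNames(list(list(), list()), c("a4", "a5")))
  cl3 <- cluster_annotations(panel)
  expect_length(cl3, 1)
  expect_equal(cl3[[1]]$support, 3)

  # two far-apart spines -> two clusters
  panel2 <- list(
    a1 = build_annotator_tracks(ann_from_boxes(1:5, c(10, 10, 20, 20))),
    a2 = build_annotator_tracks(ann_from_boxes(1:5, c(100, 100, 115, 112))))
  expect_length(cluster_annotations(panel2), 2)

  # each annotator track lands in exactly one cluster
  total <- sum(vapply(cluster_annotations(panel2),
                      function(cl) nrow(cl$members), integer(1)))
  expect_equal(total, 2)
})

test_that("representative track averages member boxes and endpoints", {
  panel <- list(
    a1 = list(const_track(1, 2, 6, c(10, 10, 20, 20))),
    a2 = list(const_track(1, 2, 8, c(14, 10, 24, 20))))
  cl <- cluster_annotations(panel)
  expect_length(cl, 1)
  rep_tr <- cl[[1]]$representative
  expect_equal(c(rep_tr$z_first, rep_tr$z_second), c(2, 7))
  expect_equal(unname(rep_tr$boxes[1, ]), c(12, 10, 22, 20))
})

test_that("ground-truth fusion selects clusters by support level", {
  mk_cluster <- function(support) {
    structure(list(members = data.frame(
      annotator = paste0("a", seq_len(support)),
      track_index = seq_len(support)),
      support = support,
      representative = const_track(0, 0, 3, c(10, 10, 20, 20))),
      class = "consensus_cluster")
  }
  cls <- list(mk_cluster(1), mk_cluster(3), mk_cluster(5))
  expect_length(fuse_ground_truth(cls, 1, n_annotators = 5), 3)
  expect_length(fuse_ground_truth(cls, 3, n_annotators = 5), 2)
  expect_length(fuse_ground_truth(cls, 5, n_annotators = 5), 1)
  expect_error(fuse_ground_truth(cls, 6, n_annotators = 5), "k must lie")
  expect_equal(unname(support_histogram(cls, 5)), c(1, 0, 1, 0, 1))
})

test_that("fused ground truths nest and identical panels score perfectly", {
  set.seed(31)
  for (rep in 1:5) {
    sim <- simulate_ground_truth(small_sim_params(seed = 300 + rep))
    panel <- make_annotator_panel(
      sim, 5, perturbation_params(corner_jitter_sd = 1, drop_prob = 0.25,
                                  spurious_rate = 0.1,
                                  seed = 7000 + rep))
    res <- consensus_ground_truth(panel, k = c(1, 3, 5),
                                  depth = sim$n_slices)
    contains <- function(sub, super) {
      all(vapply(sub, function(s) {
        any(vapply(super, function(g)
          isTRUE(all.equal(s$boxes, g$boxes)) &&
            s$z_first == g$z_first && s$z_second == g$z_second,
          logical(1)))
      }, logical(1)))
    }
    expect_true(contains(res$k5, res$k3))
    expect_true(contains(res$k3, res$k1))
  }

  # zero-noise panel: every k gives the same ground truth and every
  # annotator scores F1 = 1 against it
  sim <- simulate_ground_truth(small_sim_params(seed = 99))
  panel0 <- make_annotator_panel(
    sim, 5, perturbation_params(corner_jitter_sd = 0, drop_prob = 0,
                                spurious_rate = 0))
  res0 <- consensus_ground_truth(panel0, k = c(1, 3, 5),
                                 depth = sim$n_slices)
  expect_length(res0$k1, length(sim$tracks))
  expect_equal(summarize_tracks(res0$k1)[-1],
               summarize_tracks(res0$k5)[-1])
  for (tracks in res0$annotator_tracks) {
    for (k in c("k1", "k3", "k5")) {
      expect_equal(match_3d(tracks, res0[[k]])$f1, 1)
    }
  }
})
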