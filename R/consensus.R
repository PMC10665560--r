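#' Build 3D tracks from one annotator's per-slice labels
#'
#' Runs the same z-axis tracking used for model detections on an
#' annotator's boxes (confidence fixed at 1), so that human labels and
#' model output live in the same 3D-track representation. The same
#' two-miss termination rule applies: a label absent for two consecutive
#' slices splits the spine into two tracks.
#'
#' @param ann An [annotation_set()].
#' @param config A [pipeline_config()].
#' @param depth Stack depth; defaults to the deepest annotated slice + 1.
#' @return List of [spine_track()] objects.
#' @export
build_annotator_tracks <- function(ann, config = pipeline_config(),
                                   depth = NULL) {
  stopifnot(inherits(ann, "annotation_set"))
  b <- ann$boxes
  b$confidence <- 1
  track_stack(b, config = config, depth = depth)
}

#' Cluster the tracks of several annotators into putative spines
#'
#' Builds a graph whose vertices are all annotator tracks and whose edges
#' join tracks from *different* annotators with combined 3D IoM
#' `>= iom_threshold`, then takes single-linkage (connected-component)
#' clusters. Each annotator may contribute at most one track per cluster:
#' if two tracks of one annotator fall into the same component, the one
#' with the higher mean IoM to the other annotators' members stays and the
#' others are split out into singleton clusters. Every input track
#' therefore ends up in exactly one cluster.
#'
#' Each cluster carries a representative track: its z-interval is the
#' rounded mean of the member intervals' endpoints, and on every slice of
#' that interval its box is the coordinate-wise mean of the member boxes
#' (a member not covering the slice contributes its nearest covered box).
#'
#' @param tracks_by_annotator Named list: one list of [spine_track()]
#'   objects per annotator.
#' @param iom_threshold Overlap needed to join two tracks (default 0.5).
#' @param beta,convention Passed to [iom_3d()].
#' @return List of `consensus_cluster` objects, each with fields `members`
#'   (data frame `annotator`, `track_index`), `support` (number of
#'   distinct annotators) and `representative` (a [spine_track()]).
#' @export
cluster_annotations <- function(tracks_by_annotator, iom_threshold = 0.5,
                                beta = 0.5,
                                convention = c("slice_count", "literal")) {
  convention <- match.arg(convention)
  stopifnot(length(tracks_by_annotator) >= 1)
  if (is.null(names(tracks_by_annotator))) {
    names(tracks_by_annotator) <-
      paste0("annotator_", seq_along(tracks_by_annotator))
  }
  flat <- list()
  owner <- character(0)
  for (a in names(tracks_by_annotator)) {
    for (tr in tracks_by_annotator[[a]]) {
      flat[[length(flat) + 1L]] <- tr
      owner <- c(owner, a)
    }
  }
  n <- length(flat)
  if (n == 0L) return(list())

  S <- iom_3d_matrix(flat, flat, beta = beta, convention = convention)
  same <- outer(owner, owner, "==")
  S[same] <- 0

  # union-find single linkage
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i && S[i, j] >= iom_threshold && owner[i] != owner[j]) {
        parent[find(i)] <- find(j)
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), comp)

  # one track per annotator per cluster: keep the member with the highest
  # mean IoM to other annotators' members, split the rest out
  final_groups <- list()
  for (g in groups) {
    for (a in unique(owner[g])) {
      ga <- g[owner[g] == a]
      if (length(ga) > 1L) {
        others <- g[owner[g] != a]
        score <- vapply(ga, function(i) {
          if (length(others) == 0L) 0 else mean(S[i, others])
        }, numeric(1))
        keep <- ga[which.max(score)]
        for (i in setdiff(ga, keep)) {
          final_groups[[length(final_groups) + 1L]] <- i
          g <- setdiff(g, i)
        }
      }
    }
    final_groups[[length(final_groups) + 1L]] <- g
  }

  clusters <- lapply(final_groups, function(g) {
    members <- data.frame(annotator = owner[g], track_index = g)
    rep_track <- consensus_representative(flat[g],
                                          next_id = 0L)
    structure(list(members = members,
                   support = length(unique(owner[g])),
                   representative = rep_track),
              class = "consensus_cluster")
  })
  # deterministic order: by representative z, then x
  ord <- order(vapply(clusters, function(cl) cl$representative$z_first,
                      integer(1)),
               vapply(clusters, function(cl) cl$representative$mean_box[1],
                      numeric(1)),
               vapply(clusters, function(cl) cl$representative$mean_box[2],
                      numeric(1)))
  clusters <- clusters[ord]
  for (i in seq_along(clusters)) {
    clusters[[i]]$representative$spine_id <- i
  }
  clusters
}

#' @export
print.consensus_cluster <- function(x, ...) {
  cat(sprintf("consensus_cluster: support %d (%s), z [%d, %d]\n",
              x$support, paste(unique(x$members$annotator), collapse = ", "),
              x$representative$z_first, x$representative$z_second))
  invisible(x)
}

# representative track of a set of member tracks: z-interval = rounded
# mean of endpoints; per-slice box = mean of member boxes, each member
# clamped to its nearest covered slice
consensus_representative <- function(members, next_id = 0L) {
  z1 <- floor(mean(vapply(members, function(t) t$z_first, integer(1))) + 0.5)
  z2 <- floor(mean(vapply(members, function(t) t$z_second, integer(1))) + 0.5)
  if (z2 < z1) z2 <- z1
  slices <- z1:z2
  m <- matrix(0, nrow = length(slices), ncol = 4,
              dimnames = list(NULL, BOX_COLS))
  for (k in seq_along(slices)) {
    s <- slices[k]
    boxes <- t(vapply(members, function(t) {
      track_box_at(t, min(max(s, t$z_first), t$z_second))
    }, numeric(4)))
    m[k, ] <- colMeans(boxes)
  }
  spine_track(next_id, z1, z2, m, confidence = 1)
}

#' Fuse clustered annotations into a consensus ground truth
#'
#' Selects the representative tracks of all clusters supported by at least
#' `k` distinct annotators. With five annotators, `k = 1` gives the
#' minimal, `k = 3` the majority and `k = 5` the maximal ground truth;
#' raising `k` always yields a subset (maximal within majority within
#' minimal).
#'
#' @param clusters List of clusters from [cluster_annotations()].
#' @param k Minimum number of supporting annotators.
#' @param n_annotators Total number of annotators (for range checking);
#'   inferred from the clusters when omitted.
#' @return List of [spine_track()] objects with fresh sequential ids.
#' @export
fuse_ground_truth <- function(clusters, k, n_annotators = NULL) {
  if (is.null(n_annotators)) {
    n_annotators <- if (length(clusters) == 0L) 1L else
      length(unique(unlist(lapply(clusters,
                                  function(cl) cl$members$annotator))))
  }
  if (k < 1 || k > n_annotators) {
    stop("k must lie in 1..", n_annotators, call. = FALSE)
  }
  keep <- Filter(function(cl) cl$support >= k, clusters)
  out <- lapply(keep, function(cl) cl$representative)
  for (i in seq_along(out)) out[[i]]$spine_id <- i
  out
}

#' Histogram of cluster support counts
#'
#' @param clusters List of clusters from [cluster_annotations()].
#' @param n_annotators Number of annotators (histogram length).
#' @return Named integer vector: number of clusters supported by exactly
#'   1, 2, ..., `n_annotators` annotators.
#' @export
support_histogram <- function(clusters, n_annotators) {
  supp <- vapply(clusters, function(cl) as.integer(cl$support), integer(1))
  tab <- tabulate(supp, nbins = n_annotators)
  names(tab) <- as.character(seq_len(n_annotators))
  tab
}

#' Full consensus pipeline over annotation sets
#'
#' Convenience wrapper: builds 3D tracks per annotator, clusters them, and
#' fuses ground truths at the requested support level(s).
#'
#' @param annotation_sets List of [annotation_set()] objects.
#' @param k Support level(s); default `c(1, 3, 5)` clipped to the number
#'   of annotators.
#' @param config A [pipeline_config()]; `eval_iom_threshold` is used as
#'   the clustering threshold.
#' @param depth Stack depth passed to tracking.
#' @return Named list: `clusters`, plus one fused track list per requested
#'   `k` (named `k1`, `k3`, ...).
#' @export
consensus_ground_truth <- function(annotation_sets, k = c(1, 3, 5),
                                   config = pipeline_config(),
                                   depth = NULL) {
  config <- as_pipeline_config(config)
  tracks <- lapply(annotation_sets, build_annotator_tracks,
                   config = config, depth = depth)
  names(tracks) <- vapply(annotation_sets, function(a) a$annotator_id,
                          character(1))
  clusters <- cluster_annotations(
    tracks, iom_threshold = config$eval_iom_threshold,
    beta = config$beta, convention = config$z_length_convention)
  k <- k[k <= length(annotation_sets)]
  fused <- lapply(k, fuse_ground_truth, clusters = clusters,
                  n_annotators = length(annotation_sets))
  names(fused) <- paste0("k", k)
  c(list(clusters = clusters, annotator_tracks = tracks), fused)
}
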