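#' Intersection over Minimum along the z axis
#'
#' Overlap of two inclusive slice intervals, normalised by the shorter
#' interval. Two length conventions are supported:
#'
#' * `"slice_count"` (default): lengths are counted as numbers of slices
#'   (`z2 - z1 + 1`), and the overlap is the number of shared slices. This
#'   is well defined for single-slice intervals.
#' * `"literal"`: lengths and overlap are raw index differences
#'   (`z2 - z1`), whose denominator vanishes for single-slice intervals;
#'   in that degenerate case the score is defined as 1 when the two
#'   intervals are identical zero-length intervals and 0 otherwise.
#'
#' @param d_interval,g_interval Numeric length-2 vectors `(z1, z2)` with
#'   `z2 >= z1`, or [spine_track()] objects.
#' @param convention `"slice_count"` or `"literal"`.
#' @return Score in \[0, 1\].
#' @export
iom_z <- function(d_interval, g_interval,
                  convention = c("slice_count", "literal")) {
  convention <- match.arg(convention)
  d <- as_z_interval(d_interval)
  g <- as_z_interval(g_interval)
  if (convention == "slice_count") {
    inter <- max(0, min(d[2], g[2]) - max(d[1], g[1]) + 1)
    denom <- min(d[2] - d[1] + 1, g[2] - g[1] + 1)
    inter / denom
  } else {
    inter <- max(0, min(d[2], g[2]) - max(d[1], g[1]))
    denom <- min(d[2] - d[1], g[2] - g[1])
    if (denom == 0) {
      if (d[2] == d[1] && g[2] == g[1] && d[1] == g[1]) 1 else 0
    } else {
      inter / denom
    }
  }
}

as_z_interval <- function(x) {
  if (inherits(x, "spine_track")) x <- c(x$z_first, x$z_second)
  if (!is.numeric(x) || length(x) != 2L || x[2] < x[1]) {
    stop("a z interval is a numeric pair (z1, z2) with z2 >= z1",
         call. = FALSE)
  }
  x
}

#' Combined 3D Intersection over Minimum of two spine tracks
#'
#' Combines the in-plane overlap of the two tracks' mean boxes,
#' `x = iom_xy_2d(mean_box(d), mean_box(g))`, with the depth overlap
#' `y = iom_z(d, g)` through the F-beta weighted harmonic mean
#' `(1 + beta^2) x y / (beta^2 x + y)`. The default `beta = 0.5` gives
#' `5xy / (x + 4y)`, weighting in-plane agreement more heavily than depth
#' agreement. The score is 0 when both components vanish and 1 iff both
#' are 1; it is symmetric in its two arguments.
#'
#' @param d,g [spine_track()] objects.
#' @param beta Positive weighting parameter (default 0.5).
#' @param convention z-length convention passed to [iom_z()].
#' @return Score in \[0, 1\].
#' @export
iom_3d <- function(d, g, beta = 0.5,
                   convention = c("slice_count", "literal")) {
  x <- iom_xy_2d(mean_box(d), mean_box(g))
  y <- iom_z(d, g, convention = match.arg(convention))
  f_beta(x, y, beta)
}

# F-beta combination; first argument weighted up for beta < 1
f_beta <- function(x, y, beta = 0.5) {
  denom <- beta^2 * x + y
  ifelse(denom > 0, (1 + beta^2) * x * y / denom, 0)
}

# full combined-IoM score matrix between two track lists
iom_3d_matrix <- function(detections, gts, beta = 0.5,
                          convention = "slice_count") {
  nd <- length(detections)
  ng <- length(gts)
  S <- matrix(0, nrow = nd, ncol = ng)
  if (nd == 0L || ng == 0L) return(S)
  dm <- t(vapply(detections, mean_box, numeric(4)))
  gm <- t(vapply(gts, mean_box, numeric(4)))
  X <- pairwise_overlap(dm, gm, score = "iom")
  dz <- t(vapply(detections, function(t) c(t$z_first, t$z_second),
                 numeric(2)))
  gz <- t(vapply(gts, function(t) c(t$z_first, t$z_second), numeric(2)))
  for (i in seq_len(nd)) {
    for (j in seq_len(ng)) {
      y <- iom_z(dz[i, ], gz[j, ], convention = convention)
      S[i, j] <- f_beta(X[i, j], y, beta)
    }
  }
  S
}

#' F1 score from match counts
#'
#' `2 TP / (2 TP + FP + FN)`. The all-zero case (nothing detected,
#' nothing annotated) is reported as 0 with a warning rather than NaN;
#' empty-versus-empty comparisons should be reported, not scored.
#'
#' @param tp,fp,fn Non-negative counts.
#' @return Score in \[0, 1\].
#' @export
f1_score <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  denom <- 2 * tp + fp + fn
  if (denom == 0) {
    warning("f1_score undefined for tp = fp = fn = 0; returning 0",
            call. = FALSE)
    return(0)
  }
  2 * tp / denom
}

new_match_report <- function(tp, fp, fn, pairs, threshold, mode) {
  structure(
    list(tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
         f1 = if (tp + fp + fn == 0) 0 else f1_score(tp, fp, fn),
         pairs = pairs, threshold = threshold, mode = mode),
    class = "match_report"
  )
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("match_report (%s, threshold %.2f): TP %d, FP %d, FN %d, F1 %.4f\n",
              x$mode, x$threshold, x$tp, x$fp, x$fn, x$f1))
  invisible(x)
}

empty_pairs <- function() {
  data.frame(detection = integer(0), ground_truth = integer(0),
             score = numeric(0))
}

# Shared matching core for a score matrix S[det, gt].
# existential: a detection is TP iff some gt reaches score >= threshold; a
#   gt is missed iff no detection reaches it. This is the literal
#   definition of TP/FP/FN in 3D and can count two detections of one spine
#   as two true positives.
# one_to_one: greedy pairing by descending score, each side used at most
#   once, pairs below threshold discarded; ties break by lower detection
#   index, then lower gt index.
match_from_scores <- function(S, threshold, mode) {
  nd <- nrow(S)
  ng <- ncol(S)
  if (nd == 0L || ng == 0L) {
    return(new_match_report(0L, nd, ng, empty_pairs(), threshold, mode))
  }
  if (mode == "existential") {
    best_gt <- apply(S, 1, which.max)
    best_score <- S[cbind(seq_len(nd), best_gt)]
    is_tp <- best_score >= threshold
    fn <- sum(apply(S, 2, max) < threshold)
    pairs <- data.frame(detection = which(is_tp),
                        ground_truth = best_gt[is_tp],
                        score = best_score[is_tp])
    new_match_report(sum(is_tp), sum(!is_tp), fn, pairs, threshold, mode)
  } else {
    idx <- which(S >= threshold, arr.ind = TRUE)
    if (nrow(idx) == 0L) {
      return(new_match_report(0L, nd, ng, empty_pairs(), threshold, mode))
    }
    sc <- S[idx]
    ord <- order(-sc, idx[, 1], idx[, 2])
    used_d <- logical(nd)
    used_g <- logical(ng)
    keep <- integer(0)
    for (k in ord) {
      i <- idx[k, 1]
      j <- idx[k, 2]
      if (!used_d[i] && !used_g[j]) {
        used_d[i] <- TRUE
        used_g[j] <- TRUE
        keep <- c(keep, k)
      }
    }
    pairs <- data.frame(detection = idx[keep, 1],
                        ground_truth = idx[keep, 2], score = sc[keep])
    pairs <- pairs[order(pairs$detection), , drop = FALSE]
    rownames(pairs) <- NULL
    tp <- length(keep)
    new_match_report(tp, nd - tp, ng - tp, pairs, threshold, mode)
  }
}

#' Match 3D detections against 3D ground truth
#'
#' Compares two lists of [spine_track()] objects with the combined 3D IoM
#' ([iom_3d()]). Under the default `"existential"` mode a detection is a
#' true positive iff some ground truth reaches `IoM >= threshold` and a
#' ground truth is a false negative iff no detection reaches it; under
#' `"one_to_one"` a greedy assignment pairs each side at most once.
#'
#' @param detections,gts Lists of [spine_track()] objects.
#' @param threshold Match threshold in \[0, 1\] (default 0.5; a score of
#'   exactly 0.5 counts as a match).
#' @param mode `"existential"` or `"one_to_one"`.
#' @param beta,convention Passed to [iom_3d()].
#' @return A `match_report` with fields `tp`, `fp`, `fn`, `f1` and the
#'   matched `pairs` (detection index, ground-truth index, score).
#' @export
match_3d <- function(detections, gts, threshold = 0.5,
                     mode = c("existential", "one_to_one"),
                     beta = 0.5,
                     convention = c("slice_count", "literal")) {
  mode <- match.arg(mode)
  convention <- match.arg(convention)
  stopifnot(threshold >= 0, threshold <= 1)
  S <- iom_3d_matrix(detections, gts, beta = beta,
                     convention = convention)
  match_from_scores(S, threshold, mode)
}

#' Evaluate per-slice 2D detections against per-slice ground truth
#'
#' Matches detections and ground-truth boxes slice by slice with the
#' in-plane IoM ([iom_xy_2d()]), using the same existential or one-to-one
#' semantics as [match_3d()], and aggregates the TP/FP/FN counts over all
#' slices into a single F1.
#'
#' @param dets Detection data frame (`slice`, box columns, `confidence`).
#' @param gts Ground-truth data frame (`slice`, box columns), e.g. the
#'   `boxes` field of an [annotation_set()].
#' @param threshold IoM match threshold (default 0.5, inclusive).
#' @param mode `"existential"` or `"one_to_one"`.
#' @return A `match_report`; its `pairs` carry row indices into `dets` and
#'   `gts`.
#' @export
evaluate_2d <- function(dets, gts, threshold = 0.5,
                        mode = c("existential", "one_to_one")) {
  mode <- match.arg(mode)
  stopifnot(threshold >= 0, threshold <= 1)
  if (!"confidence" %in% names(dets)) dets$confidence <- 1
  dets <- validate_detections(dets)
  gts <- gts[c("slice", BOX_COLS)]
  tp <- 0L; fp <- 0L; fn <- 0L
  pairs <- list()
  for (s in sort(union(unique(dets$slice), unique(gts$slice)))) {
    di <- which(dets$slice == s)
    gi <- which(gts$slice == s)
    S <- pairwise_overlap(dets[di, BOX_COLS], gts[gi, BOX_COLS],
                          score = "iom")
    rep_s <- match_from_scores(S, threshold, mode)
    tp <- tp + rep_s$tp; fp <- fp + rep_s$fp; fn <- fn + rep_s$fn
    if (nrow(rep_s$pairs) > 0) {
      p <- rep_s$pairs
      p$detection <- di[p$detection]
      p$ground_truth <- gi[p$ground_truth]
      pairs[[length(pairs) + 1L]] <- p
    }
  }
  pairs <- if (length(pairs) > 0) do.call(rbind, pairs) else empty_pairs()
  new_match_report(tp, fp, fn, pairs, threshold, mode)
}

#' Serialise a match report to JSON
#'
#' @param report A `match_report` from [match_3d()] or [evaluate_2d()].
#' @param path Output JSON path.
#' @param config Optional [pipeline_config()] echoed into the report.
#' @return `path`, invisibly.
#' @export
write_match_report <- function(report, path, config = NULL) {
  stopifnot(inherits(report, "match_report"))
  out <- list(tp = report$tp, fp = report$fp, fn = report$fn,
              f1 = report$f1, threshold = report$threshold,
              mode = report$mode, pairs = report$pairs)
  if (!is.null(config)) out$config <- unclass(config)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
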