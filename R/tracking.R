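#' Match one slice of detections against active tracks
#'
#' Computes the in-plane IoM between each active track's last observed box
#' and each detection on the current slice, then greedily accepts pairs in
#' descending score order, each track and each detection used at most once,
#' only while the score strictly exceeds the threshold. Ties break by lower
#' track index, then lower detection index.
#'
#' @param active List of active tracks; each element needs a `last_box`
#'   field (a box vector). A plain list of boxes also works.
#' @param dets Detection data frame, all on one slice.
#' @param threshold IoM that a pair must strictly exceed (default 0.5).
#' @return A list with `assignments` (data frame `track`, `det`, `score` of
#'   accepted pairs, indices into the inputs), `unmatched_tracks` and
#'   `unmatched_dets` (integer index vectors).
#' @export
step_match <- function(active, dets, threshold = 0.5) {
  stopifnot(threshold >= 0, threshold <= 1)
  nt <- length(active)
  nd <- nrow(dets)
  assignments <- data.frame(track = integer(0), det = integer(0),
                            score = numeric(0))
  if (nt == 0L || nd == 0L) {
    return(list(assignments = assignments,
                unmatched_tracks = seq_len(nt),
                unmatched_dets = seq_len(nd)))
  }
  last_boxes <- t(vapply(active, function(a) {
    b <- if (is.list(a) && !is.null(a$last_box)) a$last_box else a
    as.numeric(b)
  }, numeric(4)))
  S <- pairwise_overlap(last_boxes, dets[BOX_COLS])
  idx <- which(S > threshold, arr.ind = TRUE)
  if (nrow(idx) > 0L) {
    sc <- S[idx]
    ord <- order(-sc, idx[, 1], idx[, 2])
    used_t <- logical(nt)
    used_d <- logical(nd)
    for (k in ord) {
      i <- idx[k, 1]
      j <- idx[k, 2]
      if (!used_t[i] && !used_d[j]) {
        used_t[i] <- TRUE
        used_d[j] <- TRUE
        assignments <- rbind(assignments,
                             data.frame(track = i, det = j, score = sc[k]))
      }
    }
    assignments <- assignments[order(assignments$track), , drop = FALSE]
    rownames(assignments) <- NULL
  }
  list(assignments = assignments,
       unmatched_tracks = setdiff(seq_len(nt), assignments$track),
       unmatched_dets = setdiff(seq_len(nd), assignments$det))
}

# complete a raw track state into a spine_track: gap slices between
# observed detections are filled (linear interpolation of the four
# coordinates, or carry-forward when interpolation is disabled)
finalize_track <- function(state, interpolate_gaps = TRUE) {
  h <- state$history
  z1 <- h$slice[1]
  z2 <- h$slice[nrow(h)]
  slices <- z1:z2
  m <- matrix(NA_real_, nrow = length(slices), ncol = 4,
              dimnames = list(NULL, BOX_COLS))
  obs <- h$slice - z1 + 1L
  m[obs, ] <- as.matrix(h[BOX_COLS])
  interpolated <- is.na(m[, 1])
  if (any(interpolated)) {
    if (interpolate_gaps) {
      for (k in 1:4) {
        m[, k] <- stats::approx(x = h$slice, y = h[[BOX_COLS[k]]],
                                xout = slices)$y
      }
    } else {
      for (i in which(interpolated)) {
        prev <- max(obs[obs < i])
        m[i, ] <- m[prev, ]
      }
    }
  }
  spine_track(state$id, z1, z2, m,
              confidence = max(h$confidence),
              interpolated = interpolated)
}

#' Assemble per-slice detections into 3D spine tracks
#'
#' Iterates over the stack from the top slice downward. On each slice the
#' post-processed detections are matched against the active tracks via
#' [step_match()]; matched tracks append the detection and reset their miss
#' counter, unmatched tracks count a miss and are terminated once they
#' accumulate `max_consecutive_misses` consecutive misses (default 2: a
#' track survives one missed slice and stops after its second), and
#' unmatched detections open new tracks. During a gap a track is
#' represented by its last observed box. New track ids are assigned
#' sequentially in order of first appearance, left-to-right by `x_min`
#' within a slice. At the end, each track's z-interval spans its first to
#' last actual detection, interior gap slices are filled by linear
#' interpolation of the flanking boxes (see `interpolate_gaps` in
#' [pipeline_config()]), and the track confidence is the maximum over its
#' member detections. Single-slice tracks are retained.
#'
#' @param dets Detection data frame (ideally post-processed with
#'   [postprocess_detections()]).
#' @param config A [pipeline_config()]; uses `track_match_threshold`,
#'   `max_consecutive_misses` and `interpolate_gaps`.
#' @param depth Stack depth; defaults to `max(dets$slice) + 1`.
#' @return List of [spine_track()] objects ordered by id.
#' @export
track_stack <- function(dets, config = pipeline_config(), depth = NULL) {
  config <- as_pipeline_config(config)
  dets <- validate_detections(dets, depth = depth)
  if (nrow(dets) == 0L) return(list())
  if (is.null(depth)) depth <- max(dets$slice) + 1L
  active <- list()
  finished <- list()
  next_id <- 1L
  for (s in 0:(depth - 1L)) {
    ds <- dets[dets$slice == s, , drop = FALSE]
    ds <- ds[order(ds$x_min, ds$y_min), , drop = FALSE]
    sm <- step_match(active, ds, config$track_match_threshold)
    for (r in seq_len(nrow(sm$assignments))) {
      i <- sm$assignments$track[r]
      j <- sm$assignments$det[r]
      row <- ds[j, c("slice", BOX_COLS, "confidence")]
      active[[i]]$history <- rbind(active[[i]]$history, row)
      active[[i]]$last_box <- as.numeric(row[BOX_COLS])
      active[[i]]$miss_count <- 0L
    }
    drop <- logical(length(active))
    for (i in sm$unmatched_tracks) {
      active[[i]]$miss_count <- active[[i]]$miss_count + 1L
      if (active[[i]]$miss_count >= config$max_consecutive_misses) {
        finished[[length(finished) + 1L]] <-
          finalize_track(active[[i]], config$interpolate_gaps)
        drop[i] <- TRUE
      }
    }
    if (any(drop)) active <- active[!drop]
    for (j in sm$unmatched_dets) {
      row <- ds[j, c("slice", BOX_COLS, "confidence")]
      active[[length(active) + 1L]] <- list(
        id = next_id, last_box = as.numeric(row[BOX_COLS]),
        miss_count = 0L, history = row)
      next_id <- next_id + 1L
    }
  }
  for (st in active) {
    finished[[length(finished) + 1L]] <-
      finalize_track(st, config$interpolate_gaps)
  }
  finished[order(vapply(finished, function(t) t$spine_id, integer(1)))]
}

#' Mean boxes of tracks for projection overlays
#'
#' Returns each track's mean box, keyed by spine id, for overlaying on a
#' maximum intensity projection of the stack.
#'
#' @param tracks List of [spine_track()] objects.
#' @return Data frame with columns `spine_id`, box columns, `confidence`.
#' @export
tracks_to_mip_boxes <- function(tracks) {
  if (length(tracks) == 0L) {
    return(data.frame(spine_id = integer(0), x_min = numeric(0),
                      y_min = numeric(0), x_max = numeric(0),
                      y_max = numeric(0), confidence = numeric(0)))
  }
  do.call(rbind, lapply(tracks, function(tr) {
    data.frame(spine_id = tr$spine_id, t(mean_box(tr)),
               confidence = tr$confidence, row.names = NULL)
  }))
}
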