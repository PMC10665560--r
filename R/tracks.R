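#' Construct a 3D spine track
#'
#' A spine track is one spine's footprint in a stack: an inclusive slice
#' interval `[z_first, z_second]`, one 2D box per covered slice (missed
#' interior slices are filled during tracking), the coordinate-wise mean
#' box, and an aggregate confidence.
#'
#' @param spine_id Integer identity of the spine within its stack.
#' @param z_first,z_second Inclusive 0-based slice interval,
#'   `z_second >= z_first`.
#' @param boxes Matrix or data frame of boxes with one row per slice of the
#'   interval, in slice order.
#' @param confidence Aggregate confidence in `[0, 1]` (maximum over the
#'   member detections when produced by [track_stack()]).
#' @param interpolated Logical vector flagging rows that were filled in for
#'   missed slices rather than observed (default all `FALSE`).
#' @return An object of class `spine_track` with fields `spine_id`,
#'   `z_first`, `z_second`, `boxes`, `mean_box`, `confidence`,
#'   `interpolated`.
#' @export
spine_track <- function(spine_id, z_first, z_second, boxes,
                        confidence = 1, interpolated = NULL) {
  z_first <- as.integer(z_first)
  z_second <- as.integer(z_second)
  if (z_second < z_first || z_first < 0) {
    stop("need 0 <= z_first <= z_second", call. = FALSE)
  }
  m <- as_box_matrix(boxes)
  rownames(m) <- NULL
  n <- z_second - z_first + 1L
  if (nrow(m) != n) {
    stop("boxes must have one row per slice of [z_first, z_second]",
         call. = FALSE)
  }
  validate_box(m)
  if (is.null(interpolated)) interpolated <- rep(FALSE, n)
  stopifnot(length(interpolated) == n)
  structure(
    list(spine_id = as.integer(spine_id),
         z_first = z_first, z_second = z_second,
         boxes = m, mean_box = colMeans(m),
         confidence = as.numeric(confidence),
         interpolated = as.logical(interpolated)),
    class = "spine_track"
  )
}

#' @export
print.spine_track <- function(x, ...) {
  cat(sprintf("spine_track #%d: z [%d, %d] (%d slices), conf %.3f\n",
              x$spine_id, x$z_first, x$z_second,
              x$z_second - x$z_first + 1L, x$confidence))
  invisible(x)
}

#' Mean 2D box of a track
#'
#' Coordinate-wise average of a track's per-slice boxes over the
#' `z_second - z_first + 1` covered slices. This collapses the 3D footprint
#' to a single representative rectangle for in-plane comparison.
#'
#' @param track A [spine_track()].
#' @return A named numeric box vector.
#' @export
mean_box <- function(track) {
  stopifnot(inherits(track, "spine_track"))
  colMeans(track$boxes)
}

#' Box of a track at a given slice
#'
#' @param track A [spine_track()].
#' @param slice 0-based slice index within the track's interval.
#' @return A box vector.
#' @export
track_box_at <- function(track, slice) {
  if (slice < track$z_first || slice > track$z_second) {
    stop("slice outside track interval", call. = FALSE)
  }
  track$boxes[slice - track$z_first + 1L, ]
}

track_slices <- function(track) track$z_first:track$z_second

#' Convert between track lists and flat track tables
#'
#' The flat track CSV dialect has columns `spine_id, slice, x_min, y_min,
#' x_max, y_max, interpolated, confidence` with one row per track and
#' covered slice.
#'
#' @param tracks List of [spine_track()] objects.
#' @return `tracks_to_df()` returns the flat data frame; `tracks_from_df()`
#'   rebuilds the track list.
#' @export
tracks_to_df <- function(tracks) {
  if (length(tracks) == 0L) {
    return(data.frame(spine_id = integer(0), slice = integer(0),
                      x_min = numeric(0), y_min = numeric(0),
                      x_max = numeric(0), y_max = numeric(0),
                      interpolated = integer(0), confidence = numeric(0)))
  }
  do.call(rbind, lapply(tracks, function(tr) {
    data.frame(spine_id = tr$spine_id, slice = track_slices(tr),
               tr$boxes, interpolated = as.integer(tr$interpolated),
               confidence = tr$confidence, row.names = NULL)
  }))
}

#' @rdname tracks_to_df
#' @param df A flat track table as produced by `tracks_to_df()`.
#' @export
tracks_from_df <- function(df) {
  stopifnot(all(c("spine_id", "slice", BOX_COLS) %in% names(df)))
  if (!"interpolated" %in% names(df)) df$interpolated <- 0L
  if (!"confidence" %in% names(df)) df$confidence <- 1
  ids <- unique(df$spine_id)
  lapply(ids, function(id) {
    rows <- df[df$spine_id == id, , drop = FALSE]
    rows <- rows[order(rows$slice), , drop = FALSE]
    z1 <- min(rows$slice)
    z2 <- max(rows$slice)
    if (!identical(as.integer(rows$slice), as.integer(z1:z2))) {
      stop("track ", id, " does not cover a contiguous slice interval",
           call. = FALSE)
    }
    spine_track(id, z1, z2, rows[BOX_COLS],
                confidence = max(rows$confidence),
                interpolated = rows$interpolated > 0)
  })
}

#' Read/write 3D spine tracks as CSV
#'
#' @param path CSV file path.
#' @return `read_tracks_csv()` returns a list of [spine_track()];
#'   `write_tracks_csv()` returns `path` invisibly.
#' @export
read_tracks_csv <- function(path) {
  tracks_from_df(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_tracks_csv
#' @param tracks List of [spine_track()] objects.
#' @export
write_tracks_csv <- function(tracks, path) {
  df <- tracks_to_df(tracks)
  for (nm in c(BOX_COLS, "confidence")) df[[nm]] <- round(df[[nm]], 6)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-track summary table
#'
#' @param tracks List of [spine_track()] objects.
#' @return Data frame with one row per track: id, z-interval, slice count,
#'   mean-box coordinates and confidence.
#' @export
summarize_tracks <- function(tracks) {
  if (length(tracks) == 0L) {
    return(data.frame(spine_id = integer(0), z_first = integer(0),
                      z_second = integer(0), n_slices = integer(0),
                      x_min = numeric(0), y_min = numeric(0),
                      x_max = numeric(0), y_max = numeric(0),
                      confidence = numeric(0)))
  }
  do.call(rbind, lapply(tracks, function(tr) {
    mb <- as.list(mean_box(tr))
    data.frame(spine_id = tr$spine_id, z_first = tr$z_first,
               z_second = tr$z_second,
               n_slices = tr$z_second - tr$z_first + 1L,
               mb, confidence = tr$confidence, row.names = NULL)
  }))
}
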