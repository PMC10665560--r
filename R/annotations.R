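#' Construct an annotation set
#'
#' One annotator's rectangular spine labels for a stack: a data frame of
#' per-slice boxes tagged with the annotator's identity.
#'
#' @param boxes Data frame with columns `slice`, `x_min`, `y_min`, `x_max`,
#'   `y_max` (a `confidence` column is ignored if present).
#' @param annotator_id Character label for the annotator.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(boxes, annotator_id = "annotator") {
  if (!"confidence" %in% names(boxes)) {
    boxes$confidence <- rep(1, nrow(boxes))
  }
  boxes <- validate_detections(boxes)
  structure(list(annotator_id = as.character(annotator_id),
                 boxes = boxes[c("slice", BOX_COLS)]),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set '%s': %d boxes on %d slices\n",
              x$annotator_id, nrow(x$boxes),
              length(unique(x$boxes$slice))))
  invisible(x)
}

# trailing integer in the filename stem gives the slice index
slice_from_filename <- function(filename) {
  stem <- tools::file_path_sans_ext(basename(filename))
  m <- regmatches(stem, regexpr("[0-9]+$", stem))
  if (length(m) == 0L || !nzchar(m)) {
    stop("cannot derive a slice index from filename '", filename,
         "': the stem must end in an integer", call. = FALSE)
  }
  as.integer(m)
}

#' Import rectangle annotations from a VIA project export
#'
#' Reads the JSON exported by the VGG Image Annotator (either a full
#' project file with a `_via_img_metadata` section or the bare metadata
#' dictionary). Rectangle regions with shape attributes `x`, `y`, `width`,
#' `height` are converted to boxes via `x_max = x + width`,
#' `y_max = y + height`; regions of any other shape are skipped with a
#' warning. The slice index of an image is the trailing integer of its
#' filename stem (e.g. `slice_0004.png` is slice 4).
#'
#' @param path Path to the VIA JSON document (or a JSON string).
#' @param annotator_id Annotator label to record (default: file stem).
#' @return An [annotation_set()].
#' @export
read_via_annotations <- function(path, annotator_id = NULL) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.null(doc[["_via_img_metadata"]])) doc <- doc[["_via_img_metadata"]]
  if (is.null(annotator_id)) {
    annotator_id <- if (file.exists(path)) {
      tools::file_path_sans_ext(basename(path))
    } else "annotator"
  }
  rows <- list()
  skipped <- 0L
  for (entry in doc) {
    if (is.null(entry$filename)) next
    slice <- slice_from_filename(entry$filename)
    for (region in entry$regions) {
      sa <- region$shape_attributes
      if (is.null(sa$name) || sa$name != "rect") {
        skipped <- skipped + 1L
        next
      }
      if (is.null(sa$x) || is.null(sa$y) ||
          is.null(sa$width) || is.null(sa$height)) {
        stop("rect region missing x/y/width/height attributes",
             call. = FALSE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        slice = slice,
        x_min = as.numeric(sa$x), y_min = as.numeric(sa$y),
        x_max = as.numeric(sa$x) + as.numeric(sa$width),
        y_max = as.numeric(sa$y) + as.numeric(sa$height))
    }
  }
  if (skipped > 0L) {
    warning(sprintf("skipped %d non-rectangle region(s)", skipped),
            call. = FALSE)
  }
  boxes <- if (length(rows) > 0) do.call(rbind, rows) else
    empty_detections()[c("slice", BOX_COLS)]
  ann <- annotation_set(boxes, annotator_id = annotator_id)
  attr(ann, "skipped_regions") <- skipped
  ann
}

#' Export an annotation set as VIA-style JSON
#'
#' Writes a metadata dictionary in the VIA project export layout with one
#' synthetic filename per slice (`slice_%04d.png`, whose trailing integer
#' encodes the slice index) and one rectangle region per box, so that
#' [read_via_annotations()] reproduces the input exactly.
#'
#' @param ann An [annotation_set()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_via_annotations <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_set"))
  meta <- list()
  for (s in sort(unique(ann$boxes$slice))) {
    b <- ann$boxes[ann$boxes$slice == s, , drop = FALSE]
    fname <- sprintf("slice_%04d.png", s)
    regions <- lapply(seq_len(nrow(b)), function(i) {
      list(shape_attributes = list(
             name = "rect",
             x = b$x_min[i], y = b$y_min[i],
             width = b$x_max[i] - b$x_min[i],
             height = b$y_max[i] - b$y_min[i]),
           region_attributes = list())
    })
    meta[[paste0(fname, "-1")]] <- list(filename = fname, size = -1,
                                        regions = regions,
                                        file_attributes = list())
  }
  doc <- list(`_via_img_metadata` = meta)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read/write annotation boxes as flat CSV
#'
#' The flat dialect has header `slice, x_min, y_min, x_max, y_max`
#' (0-based slices).
#'
#' @param path CSV file path.
#' @param annotator_id Annotator label (read; default: file stem).
#' @return [read_annotations_csv()] returns an [annotation_set()];
#'   [write_annotations_csv()] returns `path` invisibly.
#' @export
read_annotations_csv <- function(path, annotator_id = NULL) {
  if (is.null(annotator_id)) {
    annotator_id <- tools::file_path_sans_ext(basename(path))
  }
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  annotation_set(d, annotator_id = annotator_id)
}

#' @rdname read_annotations_csv
#' @param ann An [annotation_set()].
#' @export
write_annotations_csv <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_set"))
  b <- ann$boxes[order(ann$boxes$slice), , drop = FALSE]
  for (nm in BOX_COLS) b[[nm]] <- round(b[[nm]], 6)
  utils::write.csv(b, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
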