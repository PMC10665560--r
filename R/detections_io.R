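DET_COLS <- c("slice", BOX_COLS, "confidence")

#' Assemble a detection table
#'
#' Per-slice detections are plain data frames with columns `slice`
#' (0-based z index), `x_min`, `y_min`, `x_max`, `y_max` (continuous pixel
#' coordinates) and `confidence` in `[0, 1]`.
#'
#' @param slice Integer vector of 0-based slice indices.
#' @param boxes Boxes: data frame/matrix with box columns, or numeric(4).
#' @param confidence Numeric vector in `[0, 1]` (recycled).
#' @return A validated detection data frame.
#' @export
detections <- function(slice, boxes, confidence = 1) {
  m <- as_box_matrix(boxes)
  d <- data.frame(slice = as.integer(slice), m,
                  confidence = as.numeric(confidence))
  validate_detections(d)
}

#' Validate a detection table
#'
#' @param d Data frame with columns `slice`, `x_min`, `y_min`, `x_max`,
#'   `y_max`, `confidence`.
#' @param depth Optional stack depth; slice indices must lie in
#'   `[0, depth - 1]`.
#' @return `d` with canonical column order.
#' @export
validate_detections <- function(d, depth = NULL) {
  miss <- setdiff(DET_COLS, names(d))
  if (length(miss) > 0) {
    stop("missing detection columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  d <- d[DET_COLS]
  if (nrow(d) == 0L) return(d)
  validate_box(d)
  if (any(d$slice < 0) || any(d$slice != floor(d$slice))) {
    stop("slice indices must be non-negative integers", call. = FALSE)
  }
  if (!is.null(depth) && any(d$slice >= depth)) {
    stop("slice index outside stack depth", call. = FALSE)
  }
  if (any(!is.finite(d$confidence)) ||
      any(d$confidence < 0) || any(d$confidence > 1)) {
    stop("confidence must lie in [0, 1]", call. = FALSE)
  }
  d
}

empty_detections <- function() {
  data.frame(slice = integer(0), x_min = numeric(0), y_min = numeric(0),
             x_max = numeric(0), y_max = numeric(0), confidence = numeric(0))
}

#' Read per-slice detections from CSV
#'
#' The CSV dialect has a header row with columns `slice, x_min, y_min,
#' x_max, y_max, confidence`; slice indices are 0-based. Reading a written
#' file is lossless to 6 decimal places.
#'
#' @param path CSV file path.
#' @return A detection data frame (possibly with zero rows).
#' @export
read_detections_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_detections(d)
}

#' Write per-slice detections to CSV
#'
#' Rows are sorted by `(slice, confidence descending)` and numeric values
#' rounded to 6 decimal places before writing.
#'
#' @param d Detection data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_detections_csv <- function(d, path) {
  d <- validate_detections(d)
  d <- d[order(d$slice, -d$confidence), , drop = FALSE]
  for (nm in c(BOX_COLS, "confidence")) d[[nm]] <- round(d[[nm]], 6)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
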