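#' Filter detections by confidence
#'
#' Keeps detections whose confidence is strictly greater than the
#' threshold; only such boxes are considered real detections.
#'
#' @param dets Detection data frame.
#' @param threshold Confidence threshold in \[0, 1\] (default 0.5).
#' @return Subset of `dets` (rows unmodified).
#' @export
filter_by_confidence <- function(dets, threshold = 0.5) {
  stopifnot(threshold >= 0, threshold <= 1)
  dets[dets$confidence > threshold, , drop = FALSE]
}

#' Filter detections by box area
#'
#' Removes boxes whose area strictly exceeds the threshold. The IoM
#' divides by the smaller of the two areas being compared, so an oversized
#' detection box could spuriously score high against a small ground truth;
#' boxes larger than any plausible spine (default 2000 px, versus observed
#' spine areas of roughly 100-700 px with a maximum of 1300 px) are
#' therefore discarded.
#'
#' @param dets Detection data frame.
#' @param area_threshold_px Positive area cap in px^2 (default 2000);
#'   a box of exactly this area is kept.
#' @return Subset of `dets`.
#' @export
filter_by_area <- function(dets, area_threshold_px = 2000) {
  stopifnot(area_threshold_px > 0)
  if (nrow(dets) == 0L) return(dets)
  dets[box_area(dets) <= area_threshold_px, , drop = FALSE]
}

#' Suppress duplicate detections on one slice
#'
#' Greedy non-maximum suppression with the in-plane IoM: detections are
#' visited in order of descending confidence, and a detection is accepted
#' iff its IoM with every already-accepted detection is `<= iom_threshold`
#' (suppression requires strictly greater overlap). Among mutually
#' overlapping detections only the most confident survives.
#'
#' @param dets Detection data frame; all rows must share one slice index.
#' @param iom_threshold Overlap threshold in \[0, 1\] (default 0.5).
#' @return Subset of `dets` whose survivors have pairwise
#'   IoM `<= iom_threshold`.
#' @export
suppress_duplicates <- function(dets, iom_threshold = 0.5) {
  stopifnot(iom_threshold >= 0, iom_threshold <= 1)
  if (nrow(dets) <= 1L) return(dets)
  if (length(unique(dets$slice)) > 1L) {
    stop("suppress_duplicates expects detections from a single slice",
         call. = FALSE)
  }
  ord <- order(-dets$confidence, dets$x_min, dets$y_min)
  m <- as_box_matrix(dets)
  accepted <- integer(0)
  for (i in ord) {
    if (length(accepted) == 0L) {
      accepted <- i
      next
    }
    overlaps <- pairwise_overlap(m[i, , drop = FALSE],
                                 m[accepted, , drop = FALSE])
    if (all(overlaps <= iom_threshold)) accepted <- c(accepted, i)
  }
  dets[sort(accepted), , drop = FALSE]
}

#' Post-process the raw detections of one slice
#'
#' Applies, in order: the confidence filter, the area filter, and duplicate
#' suppression. Cheap per-box filters run first so that duplicates are
#' resolved only among plausible boxes. The composition is idempotent and
#' each stage only removes rows, never modifies boxes.
#'
#' @param dets Detection data frame for one slice.
#' @param config A [pipeline_config()].
#' @return Subset of `dets`.
#' @export
postprocess_slice <- function(dets, config = pipeline_config()) {
  config <- as_pipeline_config(config)
  dets <- filter_by_confidence(dets, config$confidence_threshold)
  dets <- filter_by_area(dets, config$area_threshold_px)
  suppress_duplicates(dets, config$duplicate_iom_threshold)
}

#' Post-process raw detections of a whole stack
#'
#' Runs [postprocess_slice()] independently on every slice present in the
#' table.
#'
#' @param dets Detection data frame covering any number of slices.
#' @param config A [pipeline_config()].
#' @return Subset of `dets`, ordered by slice.
#' @export
postprocess_detections <- function(dets, config = pipeline_config()) {
  config <- as_pipeline_config(config)
  dets <- validate_detections(dets)
  if (nrow(dets) == 0L) return(dets)
  out <- lapply(split(dets, dets$slice), postprocess_slice, config = config)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$slice), , drop = FALSE]
}
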