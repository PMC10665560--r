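#' Parameters of the classical reference detector
#'
#' Defaults were tuned once on the synthetic stack simulator.
#'
#' @param smooth_sigma Gaussian smoothing sigma in pixels (default 1.5).
#' @param threshold Absolute foreground threshold in gray levels applied
#'   after background subtraction; `NULL` (default) uses
#'   `threshold_k` standard deviations of the background-subtracted image.
#' @param threshold_k Multiplier for the adaptive threshold (default 2).
#' @param min_threshold Floor for the adaptive threshold in gray levels
#'   (default 15), guarding against blank slices where the standard
#'   deviation is pure noise.
#' @param min_area_px Components smaller than this are discarded as noise
#'   (default 15).
#' @param max_area_px Components larger than this are discarded (default
#'   2000, the same cap used for implausibly large boxes downstream).
#' @param max_elongation Components whose principal-axis elongation
#'   (square root of the eigenvalue ratio of the pixel covariance) exceeds
#'   this are discarded as dendritic shaft segments (default 4).
#' @return An object of class `reference_detector_params`.
#' @export
reference_detector_params <- function(smooth_sigma = 1.5, threshold = NULL,
                                      threshold_k = 2, min_threshold = 15,
                                      min_area_px = 15, max_area_px = 2000,
                                      max_elongation = 4) {
  stopifnot(smooth_sigma > 0, threshold_k > 0, min_area_px >= 0,
            max_area_px > min_area_px, max_elongation >= 1)
  structure(list(smooth_sigma = smooth_sigma, threshold = threshold,
                 threshold_k = threshold_k, min_threshold = min_threshold,
                 min_area_px = min_area_px, max_area_px = max_area_px,
                 max_elongation = max_elongation),
            class = "reference_detector_params")
}

component_elongation <- function(rows, cols) {
  if (length(rows) < 3L) return(1)
  cv <- stats::cov(cbind(cols, rows))
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 1e-9)
  sqrt(ev[1] / ev[2])
}

#' Classical blob-based spine detector
#'
#' A deterministic, training-free detector used as the pluggable
#' reference implementation of the detector contract: Gaussian smoothing,
#' background subtraction (median), intensity thresholding, connected
#' components, and rejection of components that are too small, too large,
#' or too elongated (dendritic shaft segments). Surviving components are
#' returned as their pixel bounding boxes with confidence equal to the
#' component's peak original intensity divided by 255.
#'
#' It deliberately trades accuracy for transparency: it exists so the
#' full pipeline can run end to end without a trained network, and as the
#' default entry in the detector registry.
#'
#' @param image 2D numeric matrix on the 0-255 gray scale
#'   (`[row = y, col = x]`).
#' @param params A [reference_detector_params()].
#' @param slice Slice index recorded on the output rows (default 0).
#' @return A detection data frame.
#' @export
reference_detect <- function(image, params = reference_detector_params(),
                             slice = 0L) {
  stopifnot(is.matrix(image))
  sm <- EBImage::gblur(image, sigma = params$smooth_sigma)
  fg <- sm - stats::median(sm)
  thr <- params$threshold
  if (is.null(thr)) {
    thr <- max(params$threshold_k * stats::sd(fg), params$min_threshold)
  }
  mask <- fg > thr
  if (!any(mask)) return(empty_detections())
  lab <- EBImage::bwlabel(mask)
  rows <- list()
  for (id in seq_len(max(lab))) {
    px <- which(lab == id, arr.ind = TRUE)
    area <- nrow(px)
    if (area < params$min_area_px || area > params$max_area_px) next
    if (component_elongation(px[, 1], px[, 2]) > params$max_elongation) next
    conf <- min(max(image[px]) / 255, 1)
    rows[[length(rows) + 1L]] <- data.frame(
      slice = as.integer(slice),
      x_min = min(px[, 2]) - 1, y_min = min(px[, 1]) - 1,
      x_max = max(px[, 2]), y_max = max(px[, 1]),
      confidence = conf)
  }
  if (length(rows) == 0L) return(empty_detections())
  validate_detections(do.call(rbind, rows))
}

# ---- detector registry ----------------------------------------------------

.detector_registry <- new.env(parent = emptyenv())

#' Register or look up a named detector
#'
#' A detector is a stateless function `(image, slice, ...) -> detection
#' data frame` mapping one 2D slice (0-255 gray matrix) to boxes with
#' confidences in `[0, 1]`. Registering under an existing name replaces
#' the previous entry. The classical [reference_detect()] is registered as
#' `"reference"` when the package loads; an adapter wrapping an external
#' CNN can be registered the same way.
#'
#' @param name Detector name.
#' @param fn Detector function.
#' @return `register_detector()` returns `fn` invisibly; `get_detector()`
#'   returns the function; `list_detectors()` the registered names.
#' @export
register_detector <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  assign(name, fn, envir = .detector_registry)
  invisible(fn)
}

#' @rdname register_detector
#' @export
get_detector <- function(name) {
  if (!exists(name, envir = .detector_registry, inherits = FALSE)) {
    stop("unknown detector '", name, "'; registered: ",
         paste(list_detectors(), collapse = ", "), call. = FALSE)
  }
  get(name, envir = .detector_registry, inherits = FALSE)
}

#' @rdname register_detector
#' @export
list_detectors <- function() {
  sort(ls(envir = .detector_registry))
}

.onLoad <- function(libname, pkgname) {
  register_detector("reference", function(image, slice = 0L, ...) {
    reference_detect(image, slice = slice, ...)
  })
}

#' Run a detector over every slice of a stack
#'
#' @param stack An [image_stack()].
#' @param detector Detector name (see [register_detector()]) or a detector
#'   function.
#' @param ... Extra arguments forwarded to the detector (e.g. `params`).
#' @return A detection data frame covering all slices, with boxes clipped
#'   to the image bounds.
#' @export
detect_stack <- function(stack, detector = "reference", ...) {
  fn <- if (is.function(detector)) detector else get_detector(detector)
  d <- dim(stack$slices[[1]])
  out <- lapply(seq_along(stack$slices) - 1L, function(s) {
    dets <- fn(stack$slices[[s + 1L]], slice = s, ...)
    dets$slice <- rep(as.integer(s), nrow(dets))
    dets
  })
  res <- do.call(rbind, out)
  if (nrow(res) > 0L) {
    res$x_min <- pmax(res$x_min, 0)
    res$y_min <- pmax(res$y_min, 0)
    res$x_max <- pmin(res$x_max, d[2])
    res$y_max <- pmin(res$y_max, d[1])
  }
  validate_detections(res, depth = n_slices(stack))
}

#' Run the full detection pipeline on a stack
#'
#' Detection on every slice, post-processing (confidence, area, duplicate
#' filters), and z-axis tracking, in one call.
#'
#' @param stack An [image_stack()].
#' @param detector Detector name or function (default `"reference"`).
#' @param config A [pipeline_config()].
#' @param ... Forwarded to the detector.
#' @return List with `detections` (raw), `filtered` (post-processed) and
#'   `tracks` (list of [spine_track()]).
#' @export
spine_pipeline <- function(stack, detector = "reference",
                           config = pipeline_config(), ...) {
  config <- as_pipeline_config(config)
  raw <- detect_stack(stack, detector = detector, ...)
  filtered <- postprocess_detections(raw, config = config)
  tracks <- track_stack(filtered, config = config, depth = n_slices(stack))
  list(detections = raw, filtered = filtered, tracks = tracks)
}
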