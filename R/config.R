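#' Pipeline configuration
#'
#' Collects every tunable threshold of the detection/tracking/evaluation
#' pipeline. Defaults are the values used throughout the package:
#'
#' * `confidence_threshold` (0.5): detections must score *strictly above*
#'   this probability to count as real detections.
#' * `duplicate_iom_threshold` (0.5): among same-slice detections with
#'   pairwise IoM strictly above this value, only the most confident one is
#'   kept.
#' * `area_threshold_px` (2000): boxes whose area strictly exceeds this are
#'   discarded; spines occupy roughly 100-700 px (at 0.1 um/px), so larger
#'   boxes are implausible and would distort the minimum-area denominator
#'   of the IoM.
#' * `track_match_threshold` (0.5): slice-to-slice IoM a detection must
#'   strictly exceed to join an existing track.
#' * `max_consecutive_misses` (2): a track survives one missed slice and is
#'   terminated after its second consecutive miss.
#' * `eval_iom_threshold` (0.5): a detection is a true positive when its
#'   IoM with some ground truth is `>=` this value.
#' * `beta` (0.5): weight of the F-beta combination of the xy and z IoM
#'   scores; 0.5 emphasises in-plane overlap over depth overlap.
#' * `z_length_convention`: `"slice_count"` (default) measures z-interval
#'   lengths as `z2 - z1 + 1`; `"literal"` uses the raw difference
#'   `z2 - z1`, which degenerates for single-slice tracks (see [iom_z()]).
#' * `matching_mode`: `"existential"` (default) or `"one_to_one"`, see
#'   [match_3d()].
#' * `interpolate_gaps`: fill missed slices inside a track by linear
#'   interpolation of the flanking boxes (default `TRUE`); when `FALSE` the
#'   last observed box is carried through the gap.
#' * `random_seed`: integer seed from which all randomness in the package
#'   flows; `NULL` leaves the RNG state untouched.
#'
#' @param confidence_threshold,duplicate_iom_threshold,area_threshold_px
#'   See details.
#' @param track_match_threshold,max_consecutive_misses,eval_iom_threshold
#'   See details.
#' @param beta,z_length_convention,matching_mode,interpolate_gaps,random_seed
#'   See details.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(confidence_threshold = 0.5,
                            duplicate_iom_threshold = 0.5,
                            area_threshold_px = 2000,
                            track_match_threshold = 0.5,
                            max_consecutive_misses = 2,
                            eval_iom_threshold = 0.5,
                            beta = 0.5,
                            z_length_convention = c("slice_count", "literal"),
                            matching_mode = c("existential", "one_to_one"),
                            interpolate_gaps = TRUE,
                            random_seed = NULL) {
  z_length_convention <- match.arg(z_length_convention)
  matching_mode <- match.arg(matching_mode)
  cfg <- list(
    confidence_threshold = confidence_threshold,
    duplicate_iom_threshold = duplicate_iom_threshold,
    area_threshold_px = area_threshold_px,
    track_match_threshold = track_match_threshold,
    max_consecutive_misses = as.integer(max_consecutive_misses),
    eval_iom_threshold = eval_iom_threshold,
    beta = beta,
    z_length_convention = z_length_convention,
    matching_mode = matching_mode,
    interpolate_gaps = isTRUE(interpolate_gaps),
    random_seed = if (is.null(random_seed)) NULL else as.integer(random_seed)
  )
  for (nm in c("confidence_threshold", "duplicate_iom_threshold",
               "track_match_threshold", "eval_iom_threshold")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1) {
      stop(nm, " must be a single value in [0, 1]", call. = FALSE)
    }
  }
  if (!is.numeric(cfg$area_threshold_px) || cfg$area_threshold_px <= 0) {
    stop("area_threshold_px must be > 0", call. = FALSE)
  }
  if (cfg$max_consecutive_misses < 0L) {
    stop("max_consecutive_misses must be >= 0", call. = FALSE)
  }
  if (!is.numeric(cfg$beta) || cfg$beta <= 0) {
    stop("beta must be > 0", call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config:\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-24s %s\n", nm,
                if (is.null(v)) "NULL" else format(v)))
  }
  invisible(x)
}

#' Read a pipeline configuration from a JSON or YAML file
#'
#' Fields mirror the arguments of [pipeline_config()]; missing fields take
#' their defaults, unknown fields are an error.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    stop("config must be .json, .yaml or .yml", call. = FALSE)
  }
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, vals)
}

as_pipeline_config <- function(config) {
  if (inherits(config, "pipeline_config")) return(config)
  if (is.list(config)) return(do.call(pipeline_config, config))
  stop("config must be a pipeline_config", call. = FALSE)
}
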