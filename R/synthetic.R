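#' Simulation parameters for synthetic spine stacks
#'
#' Defaults emulate the statistics of the two-photon dataset the pipeline
#' targets: 512 x 512 px slices at 0.1 um/px, z-step 0.5 um, stack depths
#' drawn from a normal with mean 19.5 and SD 11.5 slices truncated to
#' 5-68, spine bounding-box areas uniform in 100-700 px (hard maximum
#' 1300 px), and 8-bit intensities clipped at 255 so that dendrite cores
#' and bright spine heads saturate.
#'
#' @param image_size Slice size in pixels (square; default 512).
#' @param pixel_size_um,z_step_um Physical calibration (0.1, 0.5).
#' @param n_slices Fixed stack depth, or `NULL` (default) to sample it.
#' @param n_slices_mean,n_slices_sd,n_slices_range Depth distribution used
#'   when `n_slices` is `NULL` (truncated normal, rounded).
#' @param n_dendrites Number of dendritic branches (default 2).
#' @param n_spines Number of spines to place (default 15).
#' @param spine_area_range Range of target bounding-box areas in px on the
#'   central slice (default 100-700).
#' @param spine_area_max Hard cap on spine areas (default 1300).
#' @param spine_z_extent_range Range of z-extents in slices (default 2-7).
#' @param dendrite_width_px Shaft width (Gaussian cross-section, ~2 sigma;
#'   default 8).
#' @param spine_margin_px Minimum gap between a spine and the shaft
#'   boundary in the default separated mode (default 2).
#' @param spine_amplitude_range Peak spine intensity range in gray levels
#'   before clipping (default 140-300; values above 255 saturate).
#' @param background_level,background_noise_sd Additive background offset
#'   and Gaussian noise SD in gray levels (defaults 12 and 8).
#' @param intensity_clip Gray-value ceiling (default 255).
#' @param attached When `TRUE`, spines are drawn touching the shaft (the
#'   hard regime where detection tends to fail); by default they are
#'   separated protrusions.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(image_size = 512, pixel_size_um = 0.1,
                              z_step_um = 0.5, n_slices = NULL,
                              n_slices_mean = 19.5, n_slices_sd = 11.5,
                              n_slices_range = c(5, 68),
                              n_dendrites = 2, n_spines = 15,
                              spine_area_range = c(100, 700),
                              spine_area_max = 1300,
                              spine_z_extent_range = c(2, 7),
                              dendrite_width_px = 8, spine_margin_px = 2,
                              spine_amplitude_range = c(140, 300),
                              background_level = 12,
                              background_noise_sd = 8,
                              intensity_clip = 255, attached = FALSE,
                              seed = NULL) {
  stopifnot(image_size >= 32, pixel_size_um > 0, z_step_um > 0,
            n_dendrites >= 1, n_spines >= 0,
            spine_area_range[1] > 0,
            spine_area_range[2] >= spine_area_range[1],
            spine_area_range[2] <= spine_area_max,
            spine_z_extent_range[1] >= 1,
            dendrite_width_px > 0, spine_margin_px >= 0,
            background_noise_sd >= 0, intensity_clip > 0)
  structure(as.list(environment()), class = "simulation_params")
}

#' Annotator-perturbation parameters
#'
#' Models the variability of a human annotator relative to the true spine
#' set: whole spines missed with probability `drop_prob`, box corners
#' jittered with Gaussian noise of SD `corner_jitter_sd` px independently
#' per slice, z-interval endpoints jittered with SD `z_jitter_sd` slices,
#' and spurious boxes invented at `spurious_rate` per slice (Poisson).
#'
#' @param corner_jitter_sd Corner jitter SD in pixels (default 1).
#' @param drop_prob Probability of missing a spine entirely (default 0.05).
#' @param spurious_rate Expected invented boxes per slice (default 0.05).
#' @param z_jitter_sd SD of integer jitter of z endpoints (default 0).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return An object of class `perturbation_params`.
#' @export
perturbation_params <- function(corner_jitter_sd = 1, drop_prob = 0.05,
                                spurious_rate = 0.05, z_jitter_sd = 0,
                                seed = NULL) {
  stopifnot(corner_jitter_sd >= 0, drop_prob >= 0, drop_prob <= 1,
            spurious_rate >= 0, z_jitter_sd >= 0)
  structure(list(corner_jitter_sd = corner_jitter_sd,
                 drop_prob = drop_prob, spurious_rate = spurious_rate,
                 z_jitter_sd = z_jitter_sd,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "perturbation_params")
}

# sample(x, 1) that never falls into sample.int's scalar trap
resample1 <- function(x) x[sample.int(length(x), 1L)]

draw_n_slices <- function(p) {
  if (!is.null(p$n_slices)) return(as.integer(p$n_slices))
  n <- round(stats::rnorm(1, p$n_slices_mean, p$n_slices_sd))
  as.integer(min(max(n, p$n_slices_range[1]), p$n_slices_range[2]))
}

# a smooth random curve crossing the image, sampled at ~1.2 px spacing;
# returns an n x 2 matrix of (x, y)
draw_dendrite_curve <- function(size) {
  horizontal <- stats::runif(1) < 0.5
  main <- seq(0, size, length.out = 5)
  perp <- numeric(5)
  perp[1] <- stats::runif(1, 0.2, 0.8) * size
  for (i in 2:5) {
    perp[i] <- min(max(perp[i - 1] + stats::rnorm(1, 0, 0.10 * size),
                       0.08 * size), 0.92 * size)
  }
  f <- stats::splinefun(main, perp, method = "natural")
  t <- seq(0, size, by = 1.2)
  if (horizontal) cbind(t, f(t)) else cbind(f(t), t)
}

# z-intensity/extent profile of a spine: 1 on the central slice(s),
# shrinking toward the interval ends, never below 0.35
spine_z_profile <- function(z1, z2) {
  L <- z2 - z1 + 1L
  s <- z1:z2
  mid <- (z1 + z2) / 2
  d <- abs(s - mid)
  if (L %% 2L == 0L) d <- pmax(0, d - 0.5)
  halfspan <- (L - 1) / 2
  pmax(sqrt(pmax(1 - (d / (halfspan + 0.6))^2, 0)), 0.35)
}

min_dist_to_curve <- function(pt, curve) {
  sqrt(min((curve[, 1] - pt[1])^2 + (curve[, 2] - pt[2])^2))
}

#' Sample the geometry and ground truth of a synthetic stack
#'
#' Draws the stack depth, dendrite curves and spine placements, and
#' returns the exact 3D ground-truth tracks without rendering any pixels.
#' Spines are ellipses attached at random arc positions of a dendrite,
#' offset to the side of the shaft (separated from it by
#' `spine_margin_px` unless `attached`), with a target bounding-box area
#' drawn from `spine_area_range`, a random axis ratio in `[1, 2]` and
#' orientation along the attachment direction, and a contiguous z-extent
#' whose in-plane size peaks at the central slice. Placements are
#' rejection-sampled so that boxes stay inside the image, do not overlap
#' each other, and keep clear of other dendrites; an error is raised when
#' no non-overlapping placement can be found (too many spines for the
#' available dendrite length).
#'
#' The per-slice ground-truth boxes are the tight bounds of the spine's
#' elliptical support on that slice (shaft pixels excluded by
#' construction).
#'
#' @param params A [simulation_params()].
#' @return An object of class `spine_simulation`: list with `tracks`
#'   (ground-truth [spine_track()] list), `spines` (render geometry),
#'   `dendrites` (curve point matrices), `n_slices`, `image_size`,
#'   `params`.
#' @export
simulate_ground_truth <- function(params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  size <- params$image_size
  nz <- draw_n_slices(params)
  dendrites <- lapply(seq_len(params$n_dendrites),
                      function(i) draw_dendrite_curve(size))
  spines <- list()
  placed_boxes <- NULL
  sigma_d <- params$dendrite_width_px / 2
  for (i in seq_len(params$n_spines)) {
    ok <- FALSE
    for (attempt in seq_len(300L)) {
      di <- resample1(seq_len(params$n_dendrites))
      curve <- dendrites[[di]]
      np <- nrow(curve)
      pi_ <- resample1(seq(ceiling(np * 0.08), floor(np * 0.92)))
      p <- curve[pi_, ]
      tangent <- curve[min(pi_ + 1L, np), ] - curve[max(pi_ - 1L, 1L), ]
      tangent <- tangent / sqrt(sum(tangent^2))
      normal <- c(-tangent[2], tangent[1]) * resample1(c(-1, 1))
      A <- stats::runif(1, params$spine_area_range[1],
                        params$spine_area_range[2])
      q <- stats::runif(1, 1, 2)
      theta <- atan2(normal[2], normal[1]) + stats::rnorm(1, 0, 0.25)
      a0 <- sqrt(q)
      b0 <- 1 / sqrt(q)
      w0 <- sqrt((a0 * cos(theta))^2 + (b0 * sin(theta))^2)
      h0 <- sqrt((a0 * sin(theta))^2 + (b0 * cos(theta))^2)
      k <- sqrt(A / (4 * w0 * h0))
      w <- k * w0
      h <- k * h0
      # extent of the (axis-aligned) box along the attachment normal;
      # the shaft's bright halo reaches about two cross-section sigmas,
      # i.e. dendrite_width_px, from the curve
      ext_n <- abs(normal[1]) * w + abs(normal[2]) * h
      offset <- if (params$attached) {
        params$dendrite_width_px / 2 + ext_n / 2
      } else {
        params$dendrite_width_px + params$spine_margin_px + ext_n
      }
      ctr <- p + normal * offset
      box <- c(ctr[1] - w, ctr[2] - h, ctr[1] + w, ctr[2] + h)
      if (box[1] < 2 || box[2] < 2 || box[3] > size - 2 ||
          box[4] > size - 2) next
      if (!params$attached) {
        clear <- TRUE
        for (dj in seq_len(params$n_dendrites)) {
          if (dj == di) next
          if (min_dist_to_curve(ctr, dendrites[[dj]]) <
              params$dendrite_width_px + params$spine_margin_px +
                max(w, h)) { clear <- FALSE; break }
        }
        if (!clear) next
      }
      if (!is.null(placed_boxes)) {
        grown <- box + c(-3, -3, 3, 3)
        if (any(intersection_area(matrix(grown, nrow = 1),
                                  placed_boxes) > 0)) next
      }
      L <- min(resample1(params$spine_z_extent_range[1]:
                           params$spine_z_extent_range[2]), nz)
      z1 <- resample1(0:(nz - L))
      z2 <- z1 + L - 1L
      amp <- stats::runif(1, params$spine_amplitude_range[1],
                          params$spine_amplitude_range[2])
      spines[[i]] <- list(id = i, center = ctr, a = k * a0, b = k * b0,
                          theta = theta, w = w, h = h, amp = amp,
                          z1 = as.integer(z1), z2 = as.integer(z2))
      placed_boxes <- rbind(placed_boxes, matrix(box, nrow = 1))
      ok <- TRUE
      break
    }
    if (!ok) {
      stop("infeasible geometry: could not place spine ", i,
           " without overlap; reduce n_spines or enlarge the image",
           call. = FALSE)
    }
  }
  tracks <- lapply(spines, function(sp) {
    f <- spine_z_profile(sp$z1, sp$z2)
    m <- cbind(sp$center[1] - f * sp$w, sp$center[2] - f * sp$h,
               sp$center[1] + f * sp$w, sp$center[2] + f * sp$h)
    colnames(m) <- BOX_COLS
    spine_track(sp$id, sp$z1, sp$z2, m, confidence = 1)
  })
  structure(list(tracks = tracks, spines = spines, dendrites = dendrites,
                 n_slices = nz, image_size = size, params = params),
            class = "spine_simulation")
}

#' @export
print.spine_simulation <- function(x, ...) {
  cat(sprintf("spine_simulation: %d slices of %d px, %d dendrites, %d spines\n",
              x$n_slices, x$image_size, length(x$dendrites),
              length(x$tracks)))
  invisible(x)
}

render_dendrite_layer <- function(sim) {
  p <- sim$params
  size <- sim$image_size
  sigma_d <- p$dendrite_width_px / 2
  radius <- ceiling(3 * sigma_d)
  img <- matrix(0, size, size)
  for (curve in sim$dendrites) {
    for (i in seq_len(nrow(curve))) {
      cx <- curve[i, 1]
      cy <- curve[i, 2]
      c0 <- max(1L, floor(cx - radius))
      c1 <- min(size, ceiling(cx + radius))
      r0 <- max(1L, floor(cy - radius))
      r1 <- min(size, ceiling(cy + radius))
      if (c0 > c1 || r0 > r1) next
      dx <- (c0:c1) - 0.5 - cx
      dy <- (r0:r1) - 0.5 - cy
      K <- 330 * exp(-(outer(dy^2, dx^2, "+")) / (2 * sigma_d^2))
      img[r0:r1, c0:c1] <- pmax(img[r0:r1, c0:c1], K)
    }
  }
  img
}

render_spine_patch <- function(img, sp, f) {
  size_y <- nrow(img)
  size_x <- ncol(img)
  pad <- 3
  c0 <- max(1L, floor(sp$center[1] - f * sp$w - pad))
  c1 <- min(size_x, ceiling(sp$center[1] + f * sp$w + pad))
  r0 <- max(1L, floor(sp$center[2] - f * sp$h - pad))
  r1 <- min(size_y, ceiling(sp$center[2] + f * sp$h + pad))
  if (c0 > c1 || r0 > r1) return(img)
  dx <- (c0:c1) - 0.5 - sp$center[1]
  dy <- (r0:r1) - 0.5 - sp$center[2]
  DX <- matrix(dx, nrow = length(dy), ncol = length(dx), byrow = TRUE)
  DY <- matrix(dy, nrow = length(dy), ncol = length(dx))
  u <- (DX * cos(sp$theta) + DY * sin(sp$theta)) / (sp$a * f)
  v <- (-DX * sin(sp$theta) + DY * cos(sp$theta)) / (sp$b * f)
  K <- sp$amp * exp(-2 * (u^2 + v^2))
  img[r0:r1, c0:c1] <- pmax(img[r0:r1, c0:c1], K)
  img
}

#' Render a synthetic two-photon spine stack with known ground truth
#'
#' Samples the geometry with [simulate_ground_truth()] and renders it:
#' each dendrite is a smooth random curve drawn as a tube with Gaussian
#' cross-section whose core saturates at the clip value; each spine is a
#' blurred (Gaussian-profile) ellipse offset from the shaft, present on a
#' contiguous z-interval with intensity and in-plane extent peaking at
#' its central slice; Gaussian background noise is added and the result
#' is clipped to `[0, intensity_clip]` and rounded to 8-bit gray levels.
#' With a fixed `seed` the output is bit-identical across runs.
#'
#' @param params A [simulation_params()].
#' @return List with `stack` (an [image_stack()]), `ground_truth` (list
#'   of [spine_track()]) and `simulation` (the [simulate_ground_truth()]
#'   result).
#' @export
simulate_stack <- function(params = simulation_params()) {
  sim <- simulate_ground_truth(params)
  p <- params
  dend <- render_dendrite_layer(sim)
  profiles <- lapply(sim$spines, function(sp) spine_z_profile(sp$z1, sp$z2))
  slices <- vector("list", sim$n_slices)
  for (s in seq_len(sim$n_slices) - 1L) {
    img <- dend
    for (k in seq_along(sim$spines)) {
      sp <- sim$spines[[k]]
      if (s < sp$z1 || s > sp$z2) next
      f <- profiles[[k]][s - sp$z1 + 1L]
      img <- render_spine_patch(img, sp, f)
    }
    img <- img + p$background_level +
      stats::rnorm(length(img), 0, p$background_noise_sd)
    img <- round(pmin(pmax(img, 0), p$intensity_clip))
    slices[[s + 1L]] <- img
  }
  stack <- image_stack(slices, pixel_size_um = p$pixel_size_um,
                       z_step_um = p$z_step_um)
  list(stack = stack, ground_truth = sim$tracks, simulation = sim)
}

#' Convert ground-truth tracks to a per-slice detection table
#'
#' Useful for closure tests: a perfect detector applied to a simulated
#' stack would produce exactly these rows (confidence 1).
#'
#' @param tracks List of [spine_track()] objects.
#' @param confidence Confidence assigned to every row (default 1).
#' @return A detection data frame.
#' @export
tracks_to_detections <- function(tracks, confidence = 1) {
  df <- tracks_to_df(tracks)
  if (nrow(df) == 0L) return(empty_detections())
  data.frame(slice = df$slice, df[BOX_COLS], confidence = confidence)
}

#' Perturb a ground truth into a simulated annotator's labels
#'
#' Applies the error model of [perturbation_params()] to a set of
#' ground-truth tracks and flattens the result into per-slice boxes, as a
#' human annotator would produce: spines dropped whole, corners jittered
#' independently per slice, z endpoints jittered, and spurious boxes
#' added at random positions.
#'
#' @param gts A `spine_simulation` (from [simulate_ground_truth()]) or a
#'   list of [spine_track()] objects.
#' @param pparams A [perturbation_params()].
#' @param n_slices,image_size Stack bounds; inferred from a
#'   `spine_simulation` input, required otherwise.
#' @param annotator_id Label recorded on the output (default
#'   `"sim_annotator"`).
#' @return An [annotation_set()].
#' @export
perturb_annotations <- function(gts, pparams = perturbation_params(),
                                n_slices = NULL, image_size = NULL,
                                annotator_id = "sim_annotator") {
  if (inherits(gts, "spine_simulation")) {
    if (is.null(n_slices)) n_slices <- gts$n_slices
    if (is.null(image_size)) image_size <- gts$image_size
    gts <- gts$tracks
  }
  stopifnot(!is.null(n_slices), !is.null(image_size))
  if (!is.null(pparams$seed)) set.seed(pparams$seed)
  rows <- list()
  for (tr in gts) {
    if (stats::runif(1) < pparams$drop_prob) next
    z1 <- tr$z_first
    z2 <- tr$z_second
    if (pparams$z_jitter_sd > 0) {
      z1 <- z1 + round(stats::rnorm(1, 0, pparams$z_jitter_sd))
      z2 <- z2 + round(stats::rnorm(1, 0, pparams$z_jitter_sd))
      z1 <- min(max(z1, 0L), n_slices - 1L)
      z2 <- min(max(z2, 0L), n_slices - 1L)
      if (z2 < z1) { tmp <- z1; z1 <- z2; z2 <- tmp }
    }
    for (s in z1:z2) {
      base <- track_box_at(tr, min(max(s, tr$z_first), tr$z_second))
      b <- base + stats::rnorm(4, 0, pparams$corner_jitter_sd)
      b <- c(min(b[1], b[3]), min(b[2], b[4]),
             max(b[1], b[3]), max(b[2], b[4]))
      if (b[3] - b[1] < 1) {
        mx <- (b[1] + b[3]) / 2
        b[c(1, 3)] <- c(mx - 0.5, mx + 0.5)
      }
      if (b[4] - b[2] < 1) {
        my <- (b[2] + b[4]) / 2
        b[c(2, 4)] <- c(my - 0.5, my + 0.5)
      }
      b <- pmin(pmax(b, 0), image_size)
      rows[[length(rows) + 1L]] <- data.frame(
        slice = s, x_min = b[1], y_min = b[2], x_max = b[3], y_max = b[4])
    }
  }
  if (pparams$spurious_rate > 0) {
    for (s in 0:(n_slices - 1L)) {
      for (j in seq_len(stats::rpois(1, pparams$spurious_rate))) {
        A <- stats::runif(1, 100, 700)
        q <- stats::runif(1, 1, 2)
        w <- sqrt(A * q)
        h <- sqrt(A / q)
        cx <- stats::runif(1, w / 2 + 1, image_size - w / 2 - 1)
        cy <- stats::runif(1, h / 2 + 1, image_size - h / 2 - 1)
        rows[[length(rows) + 1L]] <- data.frame(
          slice = s, x_min = cx - w / 2, y_min = cy - h / 2,
          x_max = cx + w / 2, y_max = cy + h / 2)
      }
    }
  }
  boxes <- if (length(rows) > 0) do.call(rbind, rows) else
    empty_detections()[c("slice", BOX_COLS)]
  annotation_set(boxes, annotator_id = annotator_id)
}

#' Simulate a panel of independent annotators
#'
#' Produces `k_annotators` perturbed annotation sets over the same ground
#' truth, each with its own perturbation parameters (or a shared set with
#' derived per-annotator seeds).
#'
#' @param gts A `spine_simulation` or list of [spine_track()] objects.
#' @param k_annotators Number of annotators.
#' @param pparams A single [perturbation_params()] (its seed, when set,
#'   is offset by the annotator index) or a list of one per annotator.
#' @param n_slices,image_size Stack bounds (see [perturb_annotations()]).
#' @return List of [annotation_set()] objects named `annotator_1`, ...
#' @export
make_annotator_panel <- function(gts, k_annotators,
                                 pparams = perturbation_params(),
                                 n_slices = NULL, image_size = NULL) {
  stopifnot(k_annotators >= 1)
  if (inherits(pparams, "perturbation_params")) {
    pparams <- lapply(seq_len(k_annotators), function(i) {
      p <- pparams
      if (!is.null(p$seed)) p$seed <- p$seed + i
      p
    })
  }
  stopifnot(length(pparams) == k_annotators)
  out <- lapply(seq_len(k_annotators), function(i) {
    perturb_annotations(gts, pparams[[i]], n_slices = n_slices,
                        image_size = image_size,
                        annotator_id = paste0("annotator_", i))
  })
  names(out) <- paste0("annotator_", seq_len(k_annotators))
  out
}
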