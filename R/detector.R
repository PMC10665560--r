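#' Anchor generator configuration
#'
#' Parameters of the region-proposal anchor grid: for each stride `s` a
#' grid of centers with spacing `s` covers the image, and at each center
#' one anchor is placed per (scale, aspect ratio) combination with base
#' side `scale * s`, width `base * sqrt(ratio)` and height
#' `base / sqrt(ratio)`. Anchors may extend past the image edges and are
#' not clipped.
#'
#' @param scales Anchor scales (default 8).
#' @param strides Grid strides in pixels (default 4, 8, 16, 32, 64).
#' @param aspect_ratios Width/height ratios (default 0.5, 1, 2).
#' @param image_size Image size in pixels: a scalar for square images or
#'   `c(width, height)` (default 512).
#' @return An object of class `anchor_config`.
#' @export
anchor_config <- function(scales = 8, strides = c(4, 8, 16, 32, 64),
                          aspect_ratios = c(0.5, 1.0, 2.0),
                          image_size = 512) {
  stopifnot(all(scales > 0), all(strides > 0), all(aspect_ratios > 0),
            all(image_size > 0), length(image_size) %in% c(1L, 2L))
  if (length(image_size) == 1L) image_size <- rep(image_size, 2L)
  structure(list(scales = scales, strides = strides,
                 aspect_ratios = aspect_ratios, image_size = image_size),
            class = "anchor_config")
}

#' Closed-form anchor count
#'
#' `|ratios| * |scales| * sum_s floor(W/s) * floor(H/s)`.
#'
#' @param cfg An [anchor_config()].
#' @return Integer anchor count.
#' @export
anchor_count <- function(cfg) {
  W <- cfg$image_size[1]
  H <- cfg$image_size[2]
  length(cfg$aspect_ratios) * length(cfg$scales) *
    sum(floor(W / cfg$strides) * floor(H / cfg$strides))
}

#' Generate the anchor grid
#'
#' @param cfg An [anchor_config()].
#' @return Matrix of anchors (rows) with box columns; anchors near the
#'   border may have negative or out-of-image coordinates (unclipped), so
#'   they are plain matrices rather than validated boxes.
#' @export
generate_anchors <- function(cfg) {
  stopifnot(inherits(cfg, "anchor_config"))
  W <- cfg$image_size[1]
  H <- cfg$image_size[2]
  out <- list()
  for (s in cfg$strides) {
    nx <- floor(W / s)
    ny <- floor(H / s)
    if (nx < 1 || ny < 1) next
    cx <- s / 2 + s * (seq_len(nx) - 1)
    cy <- s / 2 + s * (seq_len(ny) - 1)
    centers <- cbind(rep(cx, times = ny), rep(cy, each = nx))
    for (scale in cfg$scales) {
      base <- scale * s
      for (r in cfg$aspect_ratios) {
        w <- base * sqrt(r)
        h <- base / sqrt(r)
        out[[length(out) + 1L]] <- cbind(
          centers[, 1] - w / 2, centers[, 2] - h / 2,
          centers[, 1] + w / 2, centers[, 2] + h / 2)
      }
    }
  }
  m <- if (length(out) > 0) do.call(rbind, out) else
    matrix(numeric(0), ncol = 4)
  colnames(m) <- BOX_COLS
  m
}

#' Assign RPN training labels to anchors
#'
#' Implements the label-assignment rule used when training a region
#' proposal network on spine boxes. Under the default `"strict"` rule, for
#' each ground-truth box the anchor with the highest IoU is labelled
#' positive iff that IoU reaches `pos_iou`; anchors whose IoU is below
#' `neg_iou` against every ground truth are labelled negative; all other
#' anchors are ignored (excluded from the loss). The `"standard"` rule of
#' the Faster R-CNN literature is available as an option: each ground
#' truth's argmax anchor is positive regardless of threshold, as is any
#' anchor with IoU `>= pos_iou` to some ground truth.
#'
#' @param anchors Matrix/data frame of anchor boxes.
#' @param gts Matrix/data frame of ground-truth boxes (may be empty).
#' @param pos_iou,neg_iou Thresholds with `0 <= neg_iou < pos_iou <= 1`
#'   (defaults 0.7 and 0.3).
#' @param rule `"strict"` (default) or `"standard"`.
#' @return Character vector over anchors with values `"positive"`,
#'   `"negative"`, `"ignore"`.
#' @export
assign_anchor_labels <- function(anchors, gts, pos_iou = 0.7,
                                 neg_iou = 0.3,
                                 rule = c("strict", "standard")) {
  rule <- match.arg(rule)
  stopifnot(neg_iou >= 0, neg_iou < pos_iou, pos_iou <= 1)
  a <- as_box_matrix(anchors)
  n <- nrow(a)
  g <- if (is.null(gts) || NROW(gts) == 0L) NULL else as_box_matrix(gts)
  if (is.null(g)) return(rep("negative", n))
  S <- pairwise_overlap(a, g, score = "iou")
  max_iou <- apply(S, 1, max)
  labels <- rep("ignore", n)
  labels[max_iou < neg_iou] <- "negative"
  for (j in seq_len(ncol(S))) {
    best <- which.max(S[, j])
    if (rule == "standard" || S[best, j] >= pos_iou) {
      labels[best] <- "positive"
    }
  }
  if (rule == "standard") labels[max_iou >= pos_iou] <- "positive"
  labels
}

#' Training constants of the detection network
#'
#' Documented, immutable defaults of the training recipe: regression loss
#' weight `alpha = 2`, L2 regularisation weight `lambda = 3e-6`, SGD
#' momentum 0.6, learning rate 1e-3, at most 1000 region proposals and 80
#' final boxes, RPN label thresholds 0.7/0.3 and proposal NMS IoU 0.7.
#'
#' @return A named list of constants.
#' @export
training_constants <- function() {
  list(alpha = 2, lambda = 3e-6, momentum = 0.6, learning_rate = 1e-3,
       n_rpn = 1000L, n_boxc = 80L, rpn_pos_iou = 0.7, rpn_neg_iou = 0.3,
       nms_iou = 0.7)
}

#' Combine the component losses of the two-stage detector
#'
#' `(l_obj_rpn + alpha * l_regr_rpn) + (l_obj_boxc + alpha * l_regr_boxc)
#' + lambda * l_regu`, i.e. the RPN and box-classifier losses each weight
#' their regression term by `alpha`, and the L2 regularisation enters with
#' weight `lambda`. Only the combination arithmetic is provided; the
#' component losses themselves belong to the training framework.
#'
#' @param l_obj_rpn,l_regr_rpn RPN objectness and regression losses.
#' @param l_obj_boxc,l_regr_boxc Box-classifier objectness and regression
#'   losses.
#' @param l_regu L2 regularisation term.
#' @param constants List with `alpha` and `lambda`
#'   (default [training_constants()]).
#' @return The combined scalar loss.
#' @export
combine_losses <- function(l_obj_rpn, l_regr_rpn, l_obj_boxc, l_regr_boxc,
                           l_regu, constants = training_constants()) {
  stopifnot(l_obj_rpn >= 0, l_regr_rpn >= 0, l_obj_boxc >= 0,
            l_regr_boxc >= 0, l_regu >= 0)
  (l_obj_rpn + constants$alpha * l_regr_rpn) +
    (l_obj_boxc + constants$alpha * l_regr_boxc) +
    constants$lambda * l_regu
}

rot90_cw <- function(m) t(m[nrow(m):1, , drop = FALSE])
hflip <- function(m) m[, ncol(m):1, drop = FALSE]

ORIENTATIONS <- do.call(rbind, lapply(0:3, function(k) {
  data.frame(rot = k, flip = c(FALSE, TRUE))
}))
ORIENTATION_NAMES <- paste0("rot", ORIENTATIONS$rot * 90,
                            ifelse(ORIENTATIONS$flip, "_hflip", ""))

apply_orientation_image <- function(image, o) {
  k <- ORIENTATIONS$rot[o]
  for (i in seq_len(k)) image <- rot90_cw(image)
  if (ORIENTATIONS$flip[o]) image <- hflip(image)
  image
}

# transform a point set (n x 2 matrix of x, y) through orientation o of an
# image of width W, height H; returns list(points, width, height) of the
# transformed frame
apply_orientation_points <- function(pts, o, W, H) {
  k <- ORIENTATIONS$rot[o]
  for (i in seq_len(k)) {
    pts <- cbind(H - pts[, 2], pts[, 1])  # clockwise quarter turn
    tmp <- W; W <- H; H <- tmp
  }
  if (ORIENTATIONS$flip[o]) pts[, 1] <- W - pts[, 1]
  list(points = pts, width = W, height = H)
}

apply_orientation_boxes <- function(boxes, o, W, H) {
  m <- as_box_matrix(boxes)
  if (nrow(m) == 0L) return(m)
  corners1 <- apply_orientation_points(m[, c(1, 2), drop = FALSE], o, W, H)
  corners2 <- apply_orientation_points(m[, c(3, 4), drop = FALSE], o, W, H)
  p1 <- corners1$points
  p2 <- corners2$points
  out <- cbind(pmin(p1[, 1], p2[, 1]), pmin(p1[, 2], p2[, 2]),
               pmax(p1[, 1], p2[, 1]), pmax(p1[, 2], p2[, 2]))
  colnames(out) <- BOX_COLS
  out
}

#' All eight orientations of an image
#'
#' The dihedral symmetries of the square: identity, three right-angle
#' clockwise rotations, and each composed with a horizontal flip. For a
#' generic (asymmetric) image the eight outputs are pairwise distinct;
#' applying any two of these transforms in sequence yields another of the
#' eight (group closure). Non-square images are allowed; shapes transpose
#' under the odd rotations.
#'
#' @param image A 2D numeric matrix.
#' @return Named list of 8 matrices (`rot0`, `rot90`, ..., `rot270_hflip`).
#' @export
enumerate_orientations <- function(image) {
  stopifnot(is.matrix(image))
  out <- lapply(seq_len(nrow(ORIENTATIONS)), function(o) {
    apply_orientation_image(image, o)
  })
  names(out) <- ORIENTATION_NAMES
  out
}

#' Randomly augment an image and its boxes
#'
#' Draws one of the eight square-symmetry orientations uniformly and
#' applies it to the image and (consistently) to the boxes, then adds
#' Gaussian white noise with probability `p_noise` and applies a Gaussian
#' blur with probability `p_blur`; the result is clipped to `[0, 255]`.
#' Randomness comes from R's global RNG, so a fixed `set.seed()` makes the
#' output reproducible. The orientation step preserves box areas exactly.
#'
#' @param image 2D numeric matrix on the 0-255 gray scale.
#' @param boxes Optional boxes (data frame/matrix) to transform alongside.
#' @param noise_sd Noise standard deviation in gray levels (default 5).
#' @param blur_sigma Blur standard deviation in pixels (default 1).
#' @param p_noise,p_blur Application probabilities (default 0.5 each).
#' @return List with `image`, `boxes`, and the applied `orientation` name.
#' @export
augment <- function(image, boxes = NULL, noise_sd = 5, blur_sigma = 1,
                    p_noise = 0.5, p_blur = 0.5) {
  stopifnot(is.matrix(image))
  H <- nrow(image)
  W <- ncol(image)
  o <- sample.int(8L, 1L)
  img <- apply_orientation_image(image, o)
  if (!is.null(boxes)) boxes <- apply_orientation_boxes(boxes, o, W, H)
  if (stats::runif(1) < p_noise) {
    img <- img + stats::rnorm(length(img), 0, noise_sd)
  }
  if (stats::runif(1) < p_blur) {
    img <- EBImage::gblur(img, sigma = blur_sigma)
  }
  img <- pmax(pmin(img, 255), 0)
  list(image = img, boxes = boxes, orientation = ORIENTATION_NAMES[o])
}
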