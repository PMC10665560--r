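BOX_COLS <- c("x_min", "y_min", "x_max", "y_max")

#' Construct an axis-aligned bounding box
#'
#' Boxes live in continuous pixel coordinates with the origin at the image's
#' top-left corner, x increasing rightward and y increasing downward. The
#' area of a box is `(x_max - x_min) * (y_max - y_min)`; no +/-1 pixel
#' adjustments are applied anywhere in the package.
#'
#' @param x_min,y_min,x_max,y_max Box edges in pixels; `x_max > x_min`,
#'   `y_max > y_min`, all finite and non-negative.
#' @return A named numeric vector of length 4 with names
#'   `x_min`, `y_min`, `x_max`, `y_max`.
#' @examples
#' b <- box2d(10, 20, 40, 35)
#' box_area(b)
#' @export
box2d <- function(x_min, y_min, x_max, y_max) {
  b <- c(x_min = as.numeric(x_min), y_min = as.numeric(y_min),
         x_max = as.numeric(x_max), y_max = as.numeric(y_max))
  validate_box(b)
  b
}

#' Validate box coordinates
#'
#' @param b A numeric vector of length 4 (`x_min`, `y_min`, `x_max`, `y_max`)
#'   or a data frame / matrix with those columns.
#' @return The input, invisibly; an error is raised on violation.
#' @export
validate_box <- function(b) {
  m <- as_box_matrix(b)
  if (any(!is.finite(m))) {
    stop("box coordinates must be finite", call. = FALSE)
  }
  if (any(m < 0)) {
    stop("box coordinates must be non-negative", call. = FALSE)
  }
  if (any(m[, 3] <= m[, 1]) || any(m[, 4] <= m[, 2])) {
    stop("boxes must satisfy x_max > x_min and y_max > y_min", call. = FALSE)
  }
  invisible(b)
}

# Coerce a box (numeric(4)), data.frame with box columns, or n x 4 matrix
# to an n x 4 numeric matrix with columns x_min, y_min, x_max, y_max.
as_box_matrix <- function(b) {
  if (is.data.frame(b)) {
    miss <- setdiff(BOX_COLS, names(b))
    if (length(miss) > 0) {
      stop("missing box columns: ", paste(miss, collapse = ", "), call. = FALSE)
    }
    m <- as.matrix(b[BOX_COLS])
  } else if (is.matrix(b)) {
    if (ncol(b) != 4L) stop("a box matrix needs 4 columns", call. = FALSE)
    m <- b
  } else {
    if (!is.numeric(b) || length(b) != 4L) {
      stop("a box is a numeric vector (x_min, y_min, x_max, y_max)",
           call. = FALSE)
    }
    m <- matrix(b, nrow = 1L)
  }
  storage.mode(m) <- "double"
  colnames(m) <- BOX_COLS
  m
}

#' Box area
#'
#' @param b A box (numeric vector of length 4), or a data frame/matrix of
#'   boxes with columns `x_min`, `y_min`, `x_max`, `y_max`.
#' @return Numeric vector of areas `(x_max - x_min) * (y_max - y_min)`.
#' @export
box_area <- function(b) {
  m <- as_box_matrix(b)
  unname((m[, 3] - m[, 1]) * (m[, 4] - m[, 2]))
}

#' Intersection area of two boxes
#'
#' Vectorised elementwise over rows when given matrices/data frames of equal
#' height (or one of height 1).
#'
#' @param b1,b2 Boxes (see [box_area()]).
#' @return Numeric vector of intersection areas (0 for disjoint boxes).
#' @export
intersection_area <- function(b1, b2) {
  m1 <- as_box_matrix(b1)
  m2 <- as_box_matrix(b2)
  if (nrow(m1) != nrow(m2)) {
    if (nrow(m1) == 1L) m1 <- m1[rep(1L, nrow(m2)), , drop = FALSE]
    else if (nrow(m2) == 1L) m2 <- m2[rep(1L, nrow(m1)), , drop = FALSE]
    else stop("incompatible numbers of boxes", call. = FALSE)
  }
  ox <- pmin(m1[, 3], m2[, 3]) - pmax(m1[, 1], m2[, 1])
  oy <- pmin(m1[, 4], m2[, 4]) - pmax(m1[, 2], m2[, 2])
  unname(pmax(0, ox) * pmax(0, oy))
}

#' Intersection over Union of two boxes
#'
#' @inheritParams intersection_area
#' @return IoU in \[0, 1\].
#' @seealso [iom_xy_2d()] for the Intersection over Minimum used throughout
#'   the spine evaluation.
#' @export
iou_2d <- function(b1, b2) {
  i <- intersection_area(b1, b2)
  u <- box_area(b1) + box_area(b2) - i
  ifelse(u > 0, i / u, 0)
}

#' Intersection over Minimum of two boxes in the image plane
#'
#' `IoM_xy(D, G) = Area(D intersect G) / min(Area(D), Area(G))`. Because
#' dendritic spines are small relative to the image, small positional
#' offsets depress the IoU strongly; dividing by the smaller area instead of
#' the union gives a score that better reflects detection quality.
#' `iom_xy_2d(b1, b2) >= iou_2d(b1, b2)` always, with value 1 whenever one
#' box contains the other.
#'
#' @inheritParams intersection_area
#' @return IoM in \[0, 1\].
#' @export
iom_xy_2d <- function(b1, b2) {
  i <- intersection_area(b1, b2)
  m <- pmin(box_area(b1), box_area(b2))
  ifelse(m > 0, i / m, 0)
}

# Pairwise overlap matrix between two sets of boxes: result[i, j] is
# fun-like score between a[i, ] and b[j, ]. score = "iom" or "iou".
pairwise_overlap <- function(a, b, score = c("iom", "iou")) {
  score <- match.arg(score)
  ma <- as_box_matrix(a)
  mb <- as_box_matrix(b)
  na <- nrow(ma)
  nb <- nrow(mb)
  if (na == 0L || nb == 0L) return(matrix(numeric(0), nrow = na, ncol = nb))
  ia <- rep(seq_len(na), times = nb)
  ib <- rep(seq_len(nb), each = na)
  inter <- intersection_area(ma[ia, , drop = FALSE], mb[ib, , drop = FALSE])
  aa <- box_area(ma)[ia]
  ab <- box_area(mb)[ib]
  denom <- if (score == "iom") pmin(aa, ab) else aa + ab - inter
  v <- ifelse(denom > 0, inter / denom, 0)
  matrix(v, nrow = na, ncol = nb)
}
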