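#' Construct an image stack
#'
#' An image stack is an ordered list of equally shaped 2D grayscale slices
#' (matrices indexed `[row = y, col = x]`, top-left origin) together with
#' the lateral pixel size and the axial step between consecutive slices.
#' Pixel values are gray levels in `[0, 255]` after preprocessing.
#'
#' @param slices List of numeric matrices, all of identical dimension.
#' @param pixel_size_um Lateral micrometres per pixel (default 0.1).
#' @param z_step_um Micrometres between consecutive slices (default 0.5).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(slices, pixel_size_um = 0.1, z_step_um = 0.5) {
  if (!is.list(slices) || length(slices) < 1L) {
    stop("an image stack needs at least one slice", call. = FALSE)
  }
  dims <- lapply(slices, dim)
  if (any(vapply(dims, is.null, logical(1)))) {
    stop("slices must be matrices", call. = FALSE)
  }
  ref <- dims[[1]]
  same <- vapply(dims, function(d) identical(d, ref), logical(1))
  if (!all(same)) {
    stop("inconsistent slice shapes in stack", call. = FALSE)
  }
  stopifnot(pixel_size_um > 0, z_step_um > 0)
  structure(
    list(slices = slices, pixel_size_um = pixel_size_um,
         z_step_um = z_step_um),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$slices[[1]])
  cat(sprintf("image_stack: %d slices of %d x %d px (%.3g um/px, z-step %.3g um)\n",
              length(x$slices), d[1], d[2], x$pixel_size_um, x$z_step_um))
  invisible(x)
}

#' Number of slices in a stack
#' @param stack An `image_stack`.
#' @return Integer slice count (stack depth).
#' @export
n_slices <- function(stack) length(stack$slices)

#' Read an image stack from disk
#'
#' Accepts either a multi-page TIFF file or a directory of single-slice
#' PNG/TIFF images; in the directory case slices are ordered by file name
#' (lexicographically), which therefore encodes the z order. Pixel values
#' are returned on the 0-255 gray scale regardless of the on-disk encoding;
#' no other value transformation is applied. Colour images are collapsed to
#' grayscale by channel averaging.
#'
#' @param path File or directory path.
#' @param pixel_size_um,z_step_um Physical calibration recorded on the stack.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, pixel_size_um = 0.1, z_step_um = 0.5) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L) {
      stop("no PNG/TIFF slices found in ", path, call. = FALSE)
    }
    slices <- lapply(files, read_slice_file)
  } else if (file.exists(path)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    slices <- lapply(pages, collapse_gray)
  } else {
    stop("no such file or directory: ", path, call. = FALSE)
  }
  image_stack(slices, pixel_size_um = pixel_size_um, z_step_um = z_step_um)
}

read_slice_file <- function(f) {
  ext <- tolower(tools::file_ext(f))
  img <- if (ext == "png") png::readPNG(f) else tiff::readTIFF(f)
  collapse_gray(img)
}

# normalize an array as returned by readPNG/readTIFF (values in [0,1],
# possibly with channels) to a 2D matrix of gray levels in [0, 255]
collapse_gray <- function(img) {
  if (length(dim(img)) == 3L) {
    nc <- min(dim(img)[3], 3L)  # drop alpha
    img <- apply(img[, , seq_len(nc), drop = FALSE], c(1, 2), mean)
  }
  img * 255
}

#' Write an image stack as a multi-page TIFF
#'
#' @param stack An [image_stack()]; values are clipped to `[0, 255]` and
#'   written as 8-bit pages.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  pages <- lapply(stack$slices, function(s) pmax(pmin(s, 255), 0) / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Clip stack intensities at a maximum gray value
#'
#' Two-photon stacks are clipped at a maximum gray value (255 for the 8-bit
#' data this package targets), which saturates a small subset of pixels
#' inside dendrites and spine heads and improves the contrast between
#' structure and noisy background. Pixels below `max_value` are unchanged;
#' the operation is idempotent.
#'
#' @param stack An [image_stack()] or a single numeric matrix.
#' @param max_value Positive gray-level ceiling (default 255).
#' @return Object of the same type with all values `<= max_value`.
#' @export
clip_intensity <- function(stack, max_value = 255) {
  stopifnot(is.numeric(max_value), length(max_value) == 1L, max_value > 0)
  if (is.matrix(stack)) return(pmin(stack, max_value))
  stack$slices <- lapply(stack$slices, pmin, max_value)
  stack
}

#' Maximum intensity projection of a stack
#'
#' @param stack An [image_stack()].
#' @return A matrix holding the per-pixel maximum over all slices.
#' @export
max_projection <- function(stack) {
  Reduce(pmax, stack$slices)
}
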