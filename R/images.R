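#' Grayscale image container
#'
#' Wraps a matrix of raw integer intensities together with its bit depth.
#' Pixels are stored as a numeric `height x width` matrix with values in
#' `[0, 2^bit_depth - 1]`; rows index the vertical (y) axis, increasing
#' downwards, columns the horizontal (x) axis.
#'
#' @param pixels numeric matrix of intensities.
#' @param bit_depth 8 or 16.
#' @return A `gray_image` object.
#' @export
gray_image <- function(pixels, bit_depth = 8L) {
  if (!is.matrix(pixels)) stop("`pixels` must be a 2-D matrix", call. = FALSE)
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) stop("image must be at least 1x1", call. = FALSE)
  if (!bit_depth %in% c(8L, 16L)) stop("bit depth must be 8 or 16", call. = FALSE)
  maxv <- 2^bit_depth - 1
  if (any(pixels < 0 | pixels > maxv)) stop("intensities outside dtype range", call. = FALSE)
  structure(list(pixels = pixels, bit_depth = as.integer(bit_depth)),
            class = "gray_image")
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d, %d-bit>\n", nrow(x$pixels), ncol(x$pixels), x$bit_depth))
  invisible(x)
}

#' Binary mask container
#'
#' A `height x width` matrix over \{0, 1\} marking root pixels as 1.
#'
#' @param pixels matrix coercible to 0/1 (values in \{0, 1\} or \{0, 255\}).
#' @return A `binary_mask` object (integer matrix with class attribute).
#' @export
binary_mask <- function(pixels) {
  if (!is.matrix(pixels)) stop("`pixels` must be a 2-D matrix", call. = FALSE)
  u <- unique(as.vector(pixels))
  if (all(u %in% c(0, 255)) && any(u == 255)) pixels <- pixels / 255
  if (!all(pixels %in% c(0, 1))) stop("mask values must be 0/1 (or 0/255)", call. = FALSE)
  m <- matrix(as.integer(pixels), nrow(pixels), ncol(pixels))
  class(m) <- c("binary_mask", class(m))
  m
}

rs_is_mask <- function(m) is.matrix(m) && all(m %in% c(0L, 1L))

#' Read a grayscale image from PNG or TIFF
#'
#' 8- and 16-bit rasters are supported; color inputs are converted to
#' luminance (Rec. 709 weights) with a warning.
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @return A [gray_image()].
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    x <- png::readPNG(path, info = TRUE)
    info <- attr(x, "info")
    depth <- if (!is.null(info$bit.depth) && info$bit.depth == 16) 16L else 8L
    x <- drop_to_gray(x, path)
    gray_image(matrix(round(x * (2^depth - 1)), nrow(x), ncol(x)), depth)
  } else if (ext %in% c("tif", "tiff")) {
    x <- tiff::readTIFF(path, as.is = TRUE)
    depth <- if (max(x) > 255) 16L else 8L
    x <- drop_to_gray(x, path)
    gray_image(matrix(as.numeric(x), nrow(x), ncol(x)), depth)
  } else {
    stop("unsupported image format: ", ext, call. = FALSE)
  }
}

drop_to_gray <- function(x, path) {
  if (length(dim(x)) == 3L) {
    if (dim(x)[3] >= 3L) {
      warning("color input converted to luminance: ", path, call. = FALSE)
      x <- 0.2126 * x[, , 1] + 0.7152 * x[, , 2] + 0.0722 * x[, , 3]
    } else {
      x <- x[, , 1]
    }
  }
  x
}

#' Read a binary ground-truth mask from a PNG (0/255 or 0/1)
#' @param path PNG file path.
#' @return A [binary_mask()].
#' @export
read_mask <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  binary_mask(matrix(as.integer(x >= 0.5), nrow(x), ncol(x)))
}

#' Write a grayscale image or binary mask as PNG
#'
#' Masks are written as 8-bit 0/255 rasters.
#'
#' @param x a [gray_image()], [binary_mask()] or numeric matrix in `[0, 1]`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(x, path) {
  m <- if (inherits(x, "gray_image")) {
    x$pixels / (2^x$bit_depth - 1)
  } else if (inherits(x, "binary_mask")) {
    matrix(as.numeric(unclass(x)), nrow(x), ncol(x))
  } else {
    x
  }
  png::writePNG(m, path)
  invisible(path)
}
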