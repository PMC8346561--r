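#' Tiling geometry for patch-based processing
#'
#' Records how a full image maps onto non-overlapping `tile_size` x
#' `tile_size` patches: the padded canvas is the smallest multiple of
#' `tile_size` covering the image in each dimension, with the original
#' content anchored at the top-left and zeros added at the bottom/right.
#'
#' @param height,width original image dimensions in pixels.
#' @param tile_size patch side length (default 256).
#' @return A `tile_grid` object with padded dimensions and tile counts.
#' @examples
#' g <- tile_grid(2665, 2345)       # 2345 x 2665 raster
#' g$n_rows * g$n_cols              # 110 tiles
#' @export
tile_grid <- function(height, width, tile_size = 256L) {
  if (tile_size < 1L) stop("tile_size must be >= 1", call. = FALSE)
  if (height < 1L || width < 1L) stop("image dimensions must be >= 1", call. = FALSE)
  ph <- as.integer(tile_size * ceiling(height / tile_size))
  pw <- as.integer(tile_size * ceiling(width / tile_size))
  structure(list(
    orig_height = as.integer(height), orig_width = as.integer(width),
    tile_size = as.integer(tile_size),
    padded_height = ph, padded_width = pw,
    n_rows = ph %/% as.integer(tile_size), n_cols = pw %/% as.integer(tile_size),
    pad_policy = "bottom_right"
  ), class = "tile_grid")
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf("<tile_grid %dx%d -> %dx%d, %d x %d tiles of %d px>\n",
              x$orig_height, x$orig_width, x$padded_height, x$padded_width,
              x$n_rows, x$n_cols, x$tile_size))
  invisible(x)
}

#' Zero-pad an image so both dimensions are divisible by the tile size
#'
#' The original content occupies the top-left region; added pixels are zero.
#'
#' @param img a [gray_image()], [binary_mask()] or plain matrix.
#' @param tile_size patch side length (default 256).
#' @return A list with `image` (padded, same type as input) and `grid`
#'   (the [tile_grid()] relating both geometries).
#' @export
pad_to_multiple <- function(img, tile_size = 256L) {
  px <- pixels_of(img)
  if (!is.matrix(px)) stop("input must be 2-dimensional", call. = FALSE)
  grid <- tile_grid(nrow(px), ncol(px), tile_size)
  out <- matrix(0, grid$padded_height, grid$padded_width)
  out[seq_len(nrow(px)), seq_len(ncol(px))] <- px
  list(image = rewrap(img, out), grid = grid)
}

pixels_of <- function(img) {
  if (inherits(img, "gray_image")) img$pixels
  else if (inherits(img, "binary_mask")) matrix(as.numeric(unclass(img)), nrow(img), ncol(img))
  else img
}

rewrap <- function(proto, px) {
  if (inherits(proto, "gray_image")) gray_image(px, proto$bit_depth)
  else if (inherits(proto, "binary_mask")) binary_mask(px)
  else px
}

#' Cut a padded image into non-overlapping patches
#'
#' Patches are emitted in row-major order (tile row varies slowest) and carry
#' 0-based `(row_index, col_index)` tile coordinates.
#'
#' @param padded padded image (dimensions divisible by `grid$tile_size`).
#' @param grid the [tile_grid()] from [pad_to_multiple()].
#' @return List of patches: `list(pixels, row_index, col_index)`.
#' @export
extract_tiles <- function(padded, grid) {
  px <- pixels_of(padded)
  ts <- grid$tile_size
  if (nrow(px) %% ts != 0L || ncol(px) %% ts != 0L)
    stop("padded dimensions are not divisible by the tile size", call. = FALSE)
  if (nrow(px) != grid$padded_height || ncol(px) != grid$padded_width)
    stop("image does not match the tile grid", call. = FALSE)
  out <- vector("list", grid$n_rows * grid$n_cols)
  k <- 1L
  for (r in seq_len(grid$n_rows) - 1L) {
    for (cc in seq_len(grid$n_cols) - 1L) {
      out[[k]] <- list(pixels = px[r * ts + seq_len(ts), cc * ts + seq_len(ts), drop = FALSE],
                       row_index = r, col_index = cc)
      k <- k + 1L
    }
  }
  out
}

#' Reassemble patches into the original (unpadded) image
#'
#' Inverse of [pad_to_multiple()] + [extract_tiles()]: for any image,
#' `stitch_tiles(extract_tiles(pad_to_multiple(x)$image, g), g)` returns `x`
#' pixel-identically.
#'
#' @param patches list of patches with 0-based tile coordinates.
#' @param grid the governing [tile_grid()].
#' @return A numeric matrix of `orig_height x orig_width` pixels.
#' @export
stitch_tiles <- function(patches, grid) {
  ts <- grid$tile_size
  seen <- matrix(FALSE, grid$n_rows, grid$n_cols)
  canvas <- matrix(0, grid$padded_height, grid$padded_width)
  for (p in patches) {
    r <- p$row_index; cc <- p$col_index
    if (r < 0L || r >= grid$n_rows || cc < 0L || cc >= grid$n_cols)
      stop("tile index outside the grid", call. = FALSE)
    if (seen[r + 1L, cc + 1L]) stop("duplicate tile (", r, ",", cc, ")", call. = FALSE)
    seen[r + 1L, cc + 1L] <- TRUE
    canvas[r * ts + seq_len(ts), cc * ts + seq_len(ts)] <- p$pixels
  }
  if (!all(seen)) stop("incomplete tile set for grid", call. = FALSE)
  canvas[seq_len(grid$orig_height), seq_len(grid$orig_width), drop = FALSE]
}

#' Scale raw patch intensities into [0, 1]
#'
#' Division by the dtype maximum (255 or 65535), so intensity contrast stays
#' comparable across patches of one image.
#'
#' @param p numeric matrix or patch list with raw intensities.
#' @param bit_depth 8 or 16.
#' @return Same structure with pixels in `[0, 1]`.
#' @export
normalize_patch <- function(p, bit_depth = 8L) {
  if (!bit_depth %in% c(8L, 16L)) stop("unknown bit depth: ", bit_depth, call. = FALSE)
  f <- function(m) m / (2^bit_depth - 1)
  if (is.list(p)) { p$pixels <- f(p$pixels); p } else f(p)
}
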