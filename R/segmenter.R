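#' Predict a per-pixel root probability map for a full image
#'
#' For tiling architectures the image is zero-padded, cut into
#' `input_size` patches, predicted in batches (batching does not change the
#' result: inference uses stored batch-norm statistics), stitched back and
#' cropped to the original dimensions. For `resize_input` architectures the
#' whole image is resized to `input_size` bilinearly, predicted in one pass,
#' and the probability map is resized back to the original dimensions by
#' bilinear interpolation before any thresholding.
#'
#' @param net a trained (or initialized) `unet_model`.
#' @param img a [gray_image()] or numeric matrix in `[0, 1]`.
#' @param batch_size tiles per forward pass.
#' @return A numeric matrix of probabilities with the original image shape.
#' @export
predict_image <- function(net, img, batch_size = 8L) {
  px <- image_unit_scale(img)
  if (nrow(px) < 1L || ncol(px) < 1L) stop("image must be at least 1x1", call. = FALSE)
  ts <- net$spec$input_size
  if (net$spec$resize_input) {
    small <- EBImage::resize(px, w = ts, h = ts)
    p <- unet_forward(net, array(small, c(ts, ts, 1L, 1L)))$p[, , 1L, 1L]
    out <- EBImage::resize(p, w = nrow(px), h = ncol(px))
    return(pmin(pmax(out, 0), 1))
  }
  padded <- pad_to_multiple(px, ts)
  tiles <- extract_tiles(padded$image, padded$grid)
  probs <- vector("list", length(tiles))
  for (b in split(seq_along(tiles), ceiling(seq_along(tiles) / batch_size))) {
    x <- array(0, c(ts, ts, 1L, length(b)))
    for (j in seq_along(b)) x[, , 1L, j] <- tiles[[b[j]]]$pixels
    p <- unet_forward(net, x)$p
    for (j in seq_along(b)) {
      probs[[b[j]]] <- list(pixels = p[, , 1L, j],
                            row_index = tiles[[b[j]]]$row_index,
                            col_index = tiles[[b[j]]]$col_index)
    }
  }
  stitch_tiles(probs, padded$grid)
}

image_unit_scale <- function(img) {
  if (inherits(img, "gray_image")) return(img$pixels / (2^img$bit_depth - 1))
  px <- pixels_of(img)
  if (!is.matrix(px)) stop("input must be a 2-D image", call. = FALSE)
  if (any(px < 0) || any(px > 1))
    stop("plain matrices must be scaled to [0, 1]; use gray_image() for raw intensities",
         call. = FALSE)
  px
}

#' Binarize a probability map
#'
#' A pixel is root iff its probability is `>= threshold` (inclusive).
#'
#' @param prob probability map in `[0, 1]`.
#' @param threshold scalar in `[0, 1]` (default 0.9, chosen high to avoid
#'   misclassifying soil as root).
#' @return A [binary_mask()].
#' @export
binarize <- function(prob, threshold = 0.9) {
  if (length(threshold) != 1L || is.na(threshold) || threshold < 0 || threshold > 1)
    stop("threshold must be a scalar in [0, 1]", call. = FALSE)
  px <- pixels_of(prob)
  binary_mask(matrix(as.integer(px >= threshold), nrow(px), ncol(px)))
}

#' Fully automated segmentation of one image
#'
#' Composition of [predict_image()] and [binarize()], recording the model id
#' and threshold for provenance.
#'
#' @inheritParams predict_image
#' @param threshold binarization threshold (default 0.9).
#' @return A `segmentation_result`: `list(prob, mask, threshold, model_id)`.
#' @export
segment <- function(net, img, threshold = 0.9, batch_size = 8L) {
  prob <- predict_image(net, img, batch_size)
  structure(list(prob = prob, mask = binarize(prob, threshold),
                 threshold = threshold, model_id = net$model_id),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation %d x %d, threshold %.2f, model %s, %.2f%% root>\n",
              nrow(x$mask), ncol(x$mask), x$threshold, x$model_id,
              100 * mean(x$mask == 1)))
  invisible(x)
}
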