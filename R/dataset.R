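#' Dilate a binary mask with a square structuring element
#'
#' Thin roots of only one or a few pixels width are easily lost when patches
#' are downsampled through the network; dilating the ground-truth masks
#' before training preserves such fine structures. The structuring element is
#' a `(2 * se_radius + 1)` square; `se_radius = 0` is the identity.
#'
#' @param m a [binary_mask()] or 0/1 matrix.
#' @param se_radius dilation radius in pixels (default 1, i.e. a 3x3 square).
#' @return A [binary_mask()] of the same shape.
#' @export
dilate_mask <- function(m, se_radius = 1L) {
  if (se_radius < 0L) stop("se_radius must be >= 0", call. = FALSE)
  mm <- pixels_of(binary_mask(pixels_of(m)))
  if (se_radius == 0L) return(binary_mask(mm))
  brush <- EBImage::makeBrush(2L * as.integer(se_radius) + 1L, shape = "box")
  binary_mask(round(EBImage::dilate(mm, brush)))
}

#' Class-balance filter for training patches
#'
#' A patch is kept only if its mask contains at least one root and one
#' background pixel (optionally at least `min_fraction` of each class), so
#' that all-background (or all-root) patches do not dominate training.
#'
#' @param mask_patch 0/1 matrix for one patch.
#' @param min_fraction minimum foreground and background fraction (default 0,
#'   i.e. one pixel of each class suffices).
#' @return `TRUE` if the patch should enter the dataset.
#' @export
keep_patch <- function(mask_patch, min_fraction = 0) {
  if (is.list(mask_patch)) mask_patch <- mask_patch$pixels
  fg <- mean(mask_patch == 1)
  fg > min_fraction && (1 - fg) > min_fraction && fg > 0 && fg < 1
}

#' Build the filtered patch dataset from image/mask pairs
#'
#' Applies, in order: mask dilation, zero-padding, tiling into
#' `tile_size` patches, intensity normalization to `[0, 1]`, and the
#' class-balance filter on the dilated mask. Output order is deterministic:
#' source order, then row-major tiles.
#'
#' @param pairs list of `list(image = gray_image, mask = binary_mask,
#'   id = <identifier>)`; `id` is optional.
#' @param tile_size patch side length (default 256).
#' @param se_radius mask dilation radius (default 1).
#' @param min_fraction class-balance threshold for [keep_patch()].
#' @return List of patch pairs `list(x, y, source_id, row_index, col_index)`
#'   where `x` is the normalized image patch and `y` the 0/1 mask patch.
#' @export
build_dataset <- function(pairs, tile_size = 256L, se_radius = 1L, min_fraction = 0) {
  out <- list()
  for (i in seq_along(pairs)) {
    pr <- pairs[[i]]
    img <- pr$image; msk <- pr$mask
    if (!identical(dim(pixels_of(img)), dim(pixels_of(msk))))
      stop("image/mask shape mismatch in pair ", i, call. = FALSE)
    id <- if (!is.null(pr$id)) pr$id else paste0("img", i)
    depth <- if (inherits(img, "gray_image")) img$bit_depth else 8L
    dm <- dilate_mask(msk, se_radius)
    pi_ <- pad_to_multiple(img, tile_size)
    pm <- pad_to_multiple(dm, tile_size)
    ti <- extract_tiles(pi_$image, pi_$grid)
    tm <- extract_tiles(pm$image, pm$grid)
    for (k in seq_along(ti)) {
      y <- tm[[k]]$pixels
      if (!keep_patch(y, min_fraction)) next
      out[[length(out) + 1L]] <- list(
        x = normalize_patch(ti[[k]]$pixels, depth),
        y = y,
        source_id = id,
        row_index = ti[[k]]$row_index,
        col_index = ti[[k]]$col_index)
    }
  }
  out
}

#' Split a patch dataset into training and validation sets
#'
#' Deterministic shuffle under `seed`, then an 85:15 split by default. Both
#' sets are guaranteed non-empty. With `by_image = TRUE` the split is applied
#' at the source-image level instead, which avoids patches of one image
#' appearing on both sides.
#'
#' @param ds patch dataset from [build_dataset()].
#' @param train_fraction fraction of patches for training (default 0.85).
#' @param seed integer RNG seed.
#' @param by_image split whole source images rather than patches.
#' @return `list(train = ..., val = ...)`.
#' @export
split_dataset <- function(ds, train_fraction = 0.85, seed = 1L, by_image = FALSE) {
  n <- length(ds)
  if (n < 2L) stop("need at least 2 patches to split", call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  if (by_image) {
    ids <- vapply(ds, function(p) as.character(p$source_id), character(1))
    uid <- unique(ids)
    if (length(uid) < 2L) stop("need at least 2 source images for a per-image split", call. = FALSE)
    k <- min(length(uid) - 1L, max(1L, round(train_fraction * length(uid))))
    tr_ids <- with_seed(seed, sample(uid)[seq_len(k)])
    return(list(train = ds[ids %in% tr_ids], val = ds[!ids %in% tr_ids]))
  }
  perm <- with_seed(seed, sample.int(n))
  k <- min(n - 1L, max(1L, round(train_fraction * n)))
  list(train = ds[perm[seq_len(k)]], val = ds[perm[(k + 1L):n]])
}

#' Read a manifest CSV of image/mask path pairs
#'
#' The manifest has columns `image_path` and `mask_path`; paths are resolved
#' relative to the manifest location when not absolute.
#'
#' @param path manifest CSV path.
#' @return List of loaded `list(image, mask, id)` pairs.
#' @export
read_manifest <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("image_path", "mask_path") %in% names(tab)))
    stop("manifest needs image_path and mask_path columns", call. = FALSE)
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  lapply(seq_len(nrow(tab)), function(i) {
    list(image = read_gray_image(resolve(tab$image_path[i])),
         mask = read_mask(resolve(tab$mask_path[i])),
         id = tools::file_path_sans_ext(basename(tab$image_path[i])))
  })
}

#' Export a patch dataset as paired PNG folders
#'
#' Writes `images/` and `masks/` subfolders plus a `manifest.csv`, a format
#' that [read_manifest()] and external tools can consume directly.
#'
#' @param ds patch dataset from [build_dataset()].
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
export_dataset <- function(ds, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(ds), function(i) {
    p <- ds[[i]]
    stem <- sprintf("%s_r%02d_c%02d.png", p$source_id, p$row_index, p$col_index)
    png::writePNG(p$x, file.path(dir, "images", stem))
    png::writePNG(matrix(as.numeric(p$y), nrow(p$y), ncol(p$y)), file.path(dir, "masks", stem))
    data.frame(image_path = file.path("images", stem),
               mask_path = file.path("masks", stem),
               source_id = p$source_id,
               row_index = p$row_index, col_index = p$col_index)
  })
  man <- do.call(rbind, rows)
  out <- file.path(dir, "manifest.csv")
  write.csv(man, out, row.names = FALSE)
  invisible(out)
}
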