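# Root-system morphometrics from a binary mask: skeletonization, branch/end
# point detection, and the 12-group / 75-trait phenotype catalogue. The
# catalogue is defined by the registry file shipped in
# inst/extdata/trait_registry.csv, not by code: the registry fixes trait
# names, grouping, order and pixel-unit dimension.

#' Skeletonize a binary root mask
#'
#' Topology-preserving Zhang-Suen thinning to a 1-px medial axis.
#' Skeleton pixels with exactly one 8-neighbor are end points (root tips);
#' branch points are pixels whose crossing number (distinct branches
#' leaving the pixel, counted as 0-to-1 transitions around its neighbor
#' ring) is three or more -- such pixels necessarily also have >= 3
#' neighbors, but the crossing number does not over-count path pixels that
#' touch several neighbors diagonally.
#' The local root width at each skeleton pixel is estimated from the
#' Euclidean distance transform as `2 * d - 1`, the diameter of the maximal
#' disc of pixel centers around the axis (a 3-px-wide bar gives width 3).
#'
#' @param mask a [binary_mask()] or 0/1 matrix; an empty mask yields an
#'   empty skeleton (not an error).
#' @return A `root_skeleton`: `pixels` (0/1 matrix), `branch_points` and
#'   `end_points` (n x 2 matrices of 1-based row/col), `width` (matrix of
#'   local widths on the skeleton, 0 elsewhere).
#' @export
skeletonize <- function(mask) {
  m <- matrix(as.integer(pixels_of(mask) != 0), nrow(pixels_of(mask)))
  if (sum(m) == 0L) {
    return(structure(list(pixels = m,
                          branch_points = matrix(0L, 0, 2),
                          end_points = matrix(0L, 0, 2),
                          width = m * 0), class = "root_skeleton"))
  }
  sk <- mm_thin(m)
  nb <- mm_neighbor_count(sk)
  cn <- mm_crossing_number(sk)
  width <- matrix(0, nrow(m), ncol(m))
  d <- as.numeric(EBImage::distmap(m, metric = "euclidean"))
  dim(d) <- dim(m)
  on_sk <- sk == 1L
  width[on_sk] <- pmax(2 * d[on_sk] - 1, 1)
  structure(list(
    pixels = sk,
    branch_points = which(on_sk & cn >= 3L, arr.ind = TRUE, useNames = FALSE),
    end_points = which(on_sk & nb == 1L, arr.ind = TRUE, useNames = FALSE),
    width = width
  ), class = "root_skeleton")
}

#' @export
print.root_skeleton <- function(x, ...) {
  cat(sprintf("<root_skeleton %d px, %d branch / %d end points>\n",
              sum(x$pixels), nrow(x$branch_points), nrow(x$end_points)))
  invisible(x)
}

#' Root area: number of root pixels
#' @param mask binary mask.
#' @return Foreground pixel count.
#' @export
trait_area <- function(mask) sum(pixels_of(mask) != 0)

#' Number of disconnected root objects (8-connected components)
#' @param mask binary mask.
#' @return Component count.
#' @export
trait_objects <- function(mask) {
  m <- matrix(as.integer(pixels_of(mask) != 0), nrow(pixels_of(mask)))
  attr(mm_label8(m), "n")
}

# Skeleton adjacencies as endpoint index pairs, scanning 4 of the 8
# directions (E, S, SE, NE) so each undirected adjacency appears once.
skeleton_steps <- function(sk) {
  H <- nrow(sk); W <- ncol(sk)
  idx <- which(sk == 1L)
  if (length(idx) == 0L)
    return(data.frame(a = integer(0), b = integer(0), len = numeric(0), vertical = logical(0)))
  r <- (idx - 1L) %% H + 1L
  cc <- (idx - 1L) %/% H + 1L
  shift <- function(dr, dc) {
    ok <- r + dr >= 1L & r + dr <= H & cc + dc >= 1L & cc + dc <= W
    j <- idx[ok] + dr + dc * H
    keep <- sk[j] == 1L
    n <- sum(keep)
    data.frame(a = idx[ok][keep], b = j[keep],
               len = rep(sqrt(dr^2 + dc^2), n),
               vertical = rep(dr != 0 & dc == 0, n))
  }
  rbind(shift(0L, 1L), shift(1L, 0L), shift(1L, 1L), shift(-1L, 1L))
}

#' Total root length from the skeleton
#'
#' Sum over skeleton adjacencies of step lengths: 1 for axial neighbors,
#' `sqrt(2)` for diagonal neighbors.
#'
#' @param skel a `root_skeleton` from [skeletonize()].
#' @return Length in pixels.
#' @export
trait_length <- function(skel) {
  sum(skeleton_steps(skel$pixels)$len)
}

#' Total root surface area and volume (cylinder model)
#'
#' Each skeleton step of length `l` with local width `w` (mean of its two
#' endpoint widths) contributes `pi * w * l` to the surface and
#' `pi * (w / 2)^2 * l` to the volume.
#'
#' @param skel a `root_skeleton` with per-pixel widths.
#' @return `c(surface = ..., volume = ...)` in px^2 / px^3.
#' @export
trait_surface_volume <- function(skel) {
  st <- skeleton_steps(skel$pixels)
  if (nrow(st) == 0L) return(c(surface = 0, volume = 0))
  w <- (skel$width[st$a] + skel$width[st$b]) / 2
  c(surface = sum(pi * w * st$len), volume = sum(pi * (w / 2)^2 * st$len))
}

# 13-number summary of an empirical distribution: location, spread, shape,
# percentiles, and a seeded bootstrap percentile interval of the mean.
# Skewness/kurtosis (classical moment form, excess kurtosis) are defined as
# 0 for constant samples.
dist_stats <- function(v, boot_seed, n_boot = 1000L) {
  if (length(v) == 0L) return(rep(0, 13))
  s <- sd(v)
  if (length(v) == 1L) s <- 0
  sk <- if (is.na(s) || s == 0) 0 else e1071::skewness(v)
  ku <- if (is.na(s) || s == 0) 0 else e1071::kurtosis(v)
  qs <- quantile(v, c(0.05, 0.25, 0.75, 0.95), names = FALSE)
  boot <- with_seed(boot_seed, {
    means <- numeric(n_boot)
    chunk <- 50L
    done <- 0L
    while (done < n_boot) {
      k <- min(chunk, n_boot - done)
      m <- matrix(sample(v, k * length(v), replace = TRUE), ncol = k)
      means[done + seq_len(k)] <- colMeans(m)
      done <- done + k
    }
    quantile(means, c(0.025, 0.975), names = FALSE)
  })
  c(mean(v), median(v), if (is.na(s)) 0 else s, sk, ku,
    min(v), qs[1], qs[2], qs[3], qs[4], max(v), boot[1], boot[2])
}

#' Distribution traits of root geometry along both image axes
#'
#' Summaries of the per-column (horizontal, x) and per-row (vertical, y)
#' root-pixel-count profiles: mean, median, standard deviation, skewness,
#' kurtosis, min/max, percentiles (5/25/75/95) and a seeded bootstrap 95%
#' interval of the profile mean. Profiles are taken over the span actually
#' occupied by roots.
#'
#' @param mask binary mask.
#' @param boot_seed seed for the bootstrap resampling.
#' @return Named vector of 26 values (13 per direction); all zeros with an
#'   `empty` attribute flag for an empty mask.
#' @export
trait_distributions <- function(mask, boot_seed = 1L) {
  m <- pixels_of(mask) != 0
  reg <- trait_registry()
  nms <- reg$trait[reg$group %in% c("x_distribution", "y_distribution")]
  if (!any(m)) return(structure(setNames(rep(0, 26), nms), empty = TRUE))
  colp <- colSums(m); colp <- colp[range(which(colp > 0))[1]:range(which(colp > 0))[2]]
  rowp <- rowSums(m); rowp <- rowp[range(which(rowp > 0))[1]:range(which(rowp > 0))[2]]
  setNames(c(dist_stats(colp, boot_seed), dist_stats(rowp, boot_seed + 1L)), nms)
}

hull_of <- function(m) {
  pts <- which(m, arr.ind = TRUE, useNames = FALSE)  # (row, col) centers
  h <- grDevices::chull(pts[, 2], pts[, 1])          # x = col, y = row
  pts[h, , drop = FALSE]
}

# Lattice points inside or on a lattice polygon, via Pick's theorem:
# count = A + B/2 + 1 (A shoelace area, B boundary lattice points).
hull_pixel_area <- function(hv) {
  n <- nrow(hv)
  if (n == 1L) return(1)
  if (n == 2L) return(gcd2(abs(hv[1, 1] - hv[2, 1]), abs(hv[1, 2] - hv[2, 2])) + 1)
  x <- hv[, 2]; y <- hv[, 1]
  j <- c(2:n, 1)
  A <- abs(sum(x * y[j] - x[j] * y)) / 2
  B <- sum(mapply(function(a, b) gcd2(a, b), abs(x - x[j]), abs(y - y[j])))
  A + B / 2 + 1
}

gcd2 <- function(a, b) {
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  max(a, 1)
}

#' Convex-hull, orientation and width traits
#'
#' Convex hull of the root pixels (pixel-counted area via Pick's theorem,
#' perimeter, solidity = area / hull area, equivalent and maximum
#' diameters); orientation of the best-fit ellipse of the foreground
#' (degrees from vertical, via the principal axis of the pixel coordinate
#' covariance) with its eccentricity; and the distribution of skeleton step
#' angles from vertical (0 = straight down, 90 = horizontal).
#'
#' @param mask binary mask.
#' @param skel optional precomputed `root_skeleton`.
#' @param boot_seed seed for the step-angle bootstrap.
#' @return Named vector of hull (5), orientation (13) and width (13) traits.
#' @export
trait_hull_orientation <- function(mask, skel = NULL, boot_seed = 1L) {
  m <- pixels_of(mask) != 0
  reg <- trait_registry()
  nms <- reg$trait[reg$group %in% c("width", "orientation", "convex_hull")]
  if (!any(m)) return(structure(setNames(rep(0, 31), nms), empty = TRUE))
  if (is.null(skel)) skel <- skeletonize(mask)

  widths <- skel$width[skel$pixels == 1L]
  width_stats <- dist_stats(widths, boot_seed + 2L)

  pts <- which(m, arr.ind = TRUE, useNames = FALSE)
  if (nrow(pts) > 1L) {
    cv <- cov(pts)
    ev <- eigen(cv, symmetric = TRUE)
    v <- ev$vectors[, 1]
    orient <- atan2(abs(v[2]), abs(v[1])) * 180 / pi
    l1 <- max(ev$values[1], 0); l2 <- max(ev$values[2], 0)
    ecc <- if (l1 > 0) sqrt(1 - l2 / l1) else 0
  } else {
    orient <- 0; ecc <- 0
  }
  st <- skeleton_steps(skel$pixels)
  ang <- if (nrow(st) > 0) {
    ifelse(st$len > 1, 45, ifelse(st$vertical, 0, 90))
  } else numeric(0)
  a <- dist_stats(ang, boot_seed + 3L)
  orient_stats <- c(orient, ecc, a[c(1:5, 8, 9, 6, 11, 12, 13)])

  hv <- hull_of(m)
  harea <- hull_pixel_area(hv)
  hperim <- if (nrow(hv) > 1) {
    j <- c(2:nrow(hv), 1)
    sum(sqrt((hv[, 1] - hv[j, 1])^2 + (hv[, 2] - hv[j, 2])^2))
  } else 0
  hmax <- if (nrow(hv) > 1) max(dist(hv)) else 0
  hull_stats <- c(harea, hperim, min(sum(m) / harea, 1), sqrt(4 * harea / pi), hmax)

  setNames(c(width_stats, orient_stats, hull_stats), nms)
}

#' Spatial extent traits
#'
#' Bounding box, centroid, rooting depth (deepest root row) and maximum
#' radial extent from the centroid.
#'
#' @param mask binary mask.
#' @return Named vector of 9 traits.
#' @export
trait_extent <- function(mask) {
  m <- pixels_of(mask) != 0
  reg <- trait_registry()
  nms <- reg$trait[reg$group == "extent"]
  if (!any(m)) return(structure(setNames(rep(0, 9), nms), empty = TRUE))
  pts <- which(m, arr.ind = TRUE, useNames = FALSE)
  rr <- range(pts[, 1]); rc <- range(pts[, 2])
  bh <- diff(rr) + 1; bw <- diff(rc) + 1
  cen <- colMeans(pts)
  rad <- sqrt(max((pts[, 1] - cen[1])^2 + (pts[, 2] - cen[2])^2))
  setNames(c(bh, bw, bh / bw, sum(m) / (bh * bw), cen[1], cen[2], rr[2], rr[1], rad), nms)
}

#' The 75-trait registry
#'
#' Reads the versioned trait catalogue: 75 named scalar traits in 12 groups,
#' with a short description and the pixel-unit dimension of each trait
#' (the power of the px-to-mm scale factor applied by `scale` in
#' [extract_traits()]).
#'
#' @return Data frame with columns `trait`, `group`, `dim`, `description`.
#' @export
trait_registry <- function() {
  path <- system.file("extdata", "trait_registry.csv", package = "rhizoseg")
  if (!nzchar(path)) path <- file.path("inst", "extdata", "trait_registry.csv")
  read.csv(path, stringsAsFactors = FALSE)
}

#' Extract the full 75-trait phenotype record from a root mask
#'
#' Assembles all trait groups into exactly 75 named scalars in registry
#' order. Deterministic given the mask and `boot_seed`. Empty masks yield a
#' flagged all-zero record rather than an error.
#'
#' @param mask binary mask (segmented root system).
#' @param boot_seed seed for the bootstrap intervals.
#' @param scale optional px-to-mm factor; trait `t` is multiplied by
#'   `scale^dim(t)` (lengths by `scale`, areas by `scale^2`, ...).
#' @return A `trait_table`: named numeric vector of length 75 with a
#'   `groups` attribute (12 levels, registry order) and an `empty` flag.
#' @export
extract_traits <- function(mask, boot_seed = 1L, scale = 1) {
  reg <- trait_registry()
  m <- pixels_of(mask) != 0
  empty <- !any(m)
  if (empty) {
    vals <- setNames(rep(0, nrow(reg)), reg$trait)
  } else {
    skel <- skeletonize(mask)
    sv <- trait_surface_volume(skel)
    scalars <- c(
      area = trait_area(mask),
      n_objects = trait_objects(mask),
      total_length = trait_length(skel),
      surface_area = unname(sv["surface"]),
      volume = unname(sv["volume"]))
    nbp <- nrow(skel$branch_points); nep <- nrow(skel$end_points)
    len <- max(scalars[["total_length"]], .Machine$double.eps)
    be <- c(n_branch_points = nbp, n_end_points = nep,
            branch_points_per_length = nbp / len,
            end_points_per_length = nep / len)
    vals <- c(scalars, be,
              trait_distributions(mask, boot_seed),
              trait_hull_orientation(mask, skel, boot_seed),
              trait_extent(mask))
    vals <- vals[reg$trait]
  }
  vals <- vals * scale^reg$dim
  structure(setNames(as.numeric(vals), reg$trait),
            groups = setNames(reg$group, reg$trait),
            empty = empty, class = "trait_table")
}

#' @export
print.trait_table <- function(x, ...) {
  g <- attr(x, "groups")
  cat(sprintf("<trait_table: %d traits in %d groups%s>\n", length(x),
              length(unique(g)), if (isTRUE(attr(x, "empty"))) ", EMPTY mask" else ""))
  print(unclass(x)[c("area", "n_objects", "total_length", "surface_area", "volume")])
  invisible(x)
}

#' Extract traits for a folder of masks into a CSV table
#'
#' @param mask_dir folder of binary PNG masks.
#' @param out_csv optional output CSV path.
#' @param scale px-to-mm factor (see [extract_traits()]).
#' @param boot_seed bootstrap seed.
#' @return Data frame: one row per image, 75 trait columns plus provenance.
#' @export
extract_traits_folder <- function(mask_dir, out_csv = NULL, scale = 1, boot_seed = 1L) {
  files <- sort(list.files(mask_dir, pattern = "\\.png$"))
  if (length(files) == 0L) stop("no masks in ", mask_dir, call. = FALSE)
  rows <- lapply(files, function(f) {
    tt <- extract_traits(read_mask(file.path(mask_dir, f)), boot_seed, scale)
    cbind(data.frame(image = f, scale = scale, boot_seed = boot_seed),
          as.data.frame(as.list(unclass(tt))))
  })
  tab <- do.call(rbind, rows)
  if (!is.null(out_csv)) write.csv(tab, out_csv, row.names = FALSE)
  tab
}
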