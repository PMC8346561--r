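#' Dice coefficient between predicted and ground-truth masks
#'
#' `DC = 2 |P intersect G| / (|P| + |G|)`, computed from pixel sums. Two
#' empty masks agree perfectly and return 1 (with a `"degenerate"` attribute
#' flag). Probability maps can be passed together with `threshold` to
#' binarize first.
#'
#' @param pred,truth binary masks (0/1 matrices) of identical shape.
#' @param threshold optional: binarize `pred` at this probability first.
#' @return Dice coefficient in `[0, 1]`.
#' @examples
#' a <- matrix(c(1, 1, 0, 0), 2)
#' b <- matrix(c(1, 0, 1, 0), 2)
#' dice(a, b)  # overlap 1 of 2+2 -> 0.5
#' @export
dice <- function(pred, truth, threshold = NULL) {
  if (!is.null(threshold)) pred <- binarize(pred, threshold)
  pred <- pixels_of(pred); truth <- pixels_of(truth)
  check_mask_pair(pred, truth)
  s <- sum(pred) + sum(truth)
  if (s == 0) return(structure(1, degenerate = TRUE))
  2 * sum(pred * truth) / s
}

#' Precision and recall of a predicted mask
#'
#' Precision is the fraction of predicted root pixels that are truly root
#' (`TP / (TP + FP)`); recall is the fraction of true root pixels recovered
#' (`TP / (TP + FN)`). An empty denominator returns the sentinel 1 with a
#' `"degenerate"` attribute flag and a warning.
#'
#' @inheritParams dice
#' @return `c(precision = ..., recall = ...)`.
#' @export
precision_recall <- function(pred, truth, threshold = NULL) {
  if (!is.null(threshold)) pred <- binarize(pred, threshold)
  pred <- pixels_of(pred); truth <- pixels_of(truth)
  check_mask_pair(pred, truth)
  tp <- sum(pred * truth)
  pp <- sum(pred); tg <- sum(truth)
  deg <- FALSE
  if (pp == 0) { warning("no predicted root pixels; precision set to 1", call. = FALSE); deg <- TRUE }
  if (tg == 0) { warning("no true root pixels; recall set to 1", call. = FALSE); deg <- TRUE }
  out <- c(precision = if (pp == 0) 1 else tp / pp,
           recall = if (tg == 0) 1 else tp / tg)
  if (deg) attr(out, "degenerate") <- TRUE
  out
}

#' Dice from precision and recall (harmonic-mean identity)
#'
#' `DC = 2 * precision * recall / (precision + recall)`; equal (to floating
#' tolerance) to [dice()] computed directly on the same mask pair.
#'
#' @param precision,recall scalars in `[0, 1]`, not both zero.
#' @return Dice coefficient.
#' @export
dice_from_pr <- function(precision, recall) {
  if (precision + recall <= 0) stop("Dice undefined: precision + recall is zero", call. = FALSE)
  unname(2 * precision * recall / (precision + recall))
}

#' Full confusion-count summary for a mask pair
#'
#' @inheritParams dice
#' @return A `seg_metrics` list: `dice`, `precision`, `recall`, `bce`,
#'   `n_pixels`, `intersection`, `pred_sum`, `truth_sum`.
#' @export
seg_metrics <- function(pred, truth, threshold = NULL) {
  prob <- NULL
  if (!is.null(threshold)) { prob <- pixels_of(pred); pred <- binarize(pred, threshold) }
  pred <- pixels_of(pred); truth <- pixels_of(truth)
  check_mask_pair(pred, truth)
  pr <- suppressWarnings(precision_recall(pred, truth))
  structure(list(
    dice = as.numeric(dice(pred, truth)),
    precision = unname(pr["precision"]), recall = unname(pr["recall"]),
    bce = if (is.null(prob)) NA_real_ else bce_loss(prob, truth),
    n_pixels = length(pred),
    intersection = sum(pred * truth),
    pred_sum = sum(pred), truth_sum = sum(truth)
  ), class = "seg_metrics")
}

check_mask_pair <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    stop("prediction and ground truth have different shapes", call. = FALSE)
  invisible(TRUE)
}

#' Evaluate folders of predicted vs ground-truth masks
#'
#' Pairs files by name, computes per-image Dice/precision/recall and appends
#' a mean row, mirroring per-image evaluation tables.
#'
#' @param pred_dir,truth_dir folders of PNG masks with matching file names.
#' @param out_csv optional path to write the table to.
#' @return A data.frame with one row per image plus a `"mean"` row.
#' @export
evaluate_mask_folders <- function(pred_dir, truth_dir, out_csv = NULL) {
  files <- sort(list.files(truth_dir, pattern = "\\.png$"))
  if (length(files) == 0L) stop("no ground-truth masks in ", truth_dir, call. = FALSE)
  rows <- lapply(files, function(f) {
    pf <- file.path(pred_dir, f)
    if (!file.exists(pf)) stop("missing prediction for ", f, call. = FALSE)
    p <- read_mask(pf); g <- read_mask(file.path(truth_dir, f))
    pr <- suppressWarnings(precision_recall(p, g))
    data.frame(image = f, dice = as.numeric(dice(p, g)),
               precision = unname(pr["precision"]), recall = unname(pr["recall"]))
  })
  tab <- do.call(rbind, rows)
  tab <- rbind(tab, data.frame(image = "mean", dice = mean(tab$dice),
                               precision = mean(tab$precision), recall = mean(tab$recall)))
  if (!is.null(out_csv)) write.csv(tab, out_csv, row.names = FALSE)
  tab
}
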