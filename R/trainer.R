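#' Binary cross-entropy loss
#'
#' Mean over pixels of `-[g log p + (1 - g) log(1 - p)]`, with predictions
#' clipped away from 0/1 at machine epsilon.
#'
#' @param pred probabilities in `[0, 1]` (matrix or array).
#' @param truth 0/1 labels of the same shape.
#' @return Non-negative scalar loss.
#' @export
bce_loss <- function(pred, truth) {
  pred <- pixels_of(pred); truth <- pixels_of(truth)
  if (!identical(dim(pred), dim(truth)))
    stop("prediction and ground truth have different shapes", call. = FALSE)
  eps <- .Machine$double.eps
  p <- pmin(pmax(pred, eps), 1 - eps)
  -mean(truth * log(p) + (1 - truth) * log(1 - p))
}

#' Training configuration
#'
#' Defaults follow the reference training protocol: Adam with learning rate
#' 0.001, batch size 128 and up to 200 epochs, monitoring the validation
#' Dice coefficient for best-epoch selection. The batch size is clipped to
#' the dataset size with a warning when the dataset is smaller.
#'
#' @param learning_rate Adam step size (> 0).
#' @param batch_size minibatch size (>= 1).
#' @param max_epochs maximum epochs (>= 1).
#' @param seed RNG seed controlling shuffling.
#' @param monitor metric used for checkpointing (only `"val_dice"`).
#' @param patience optional early-stopping patience in epochs (default off).
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 128L,
                         max_epochs = 200L, seed = 1L, monitor = "val_dice",
                         patience = Inf) {
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1)
  monitor <- match.arg(monitor, "val_dice")
  structure(list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), seed = as.integer(seed),
                 monitor = monitor, patience = patience),
            class = "train_config")
}

# Adam with canonical moment parameters; only the learning rate is tuned.
ADAM_BETA1 <- 0.9
ADAM_BETA2 <- 0.999
ADAM_EPS <- 1e-7

adam_init <- function(params) {
  list(m = lapply(params, function(p) { p[] <- 0; p }),
       v = lapply(params, function(p) { p[] <- 0; p }),
       t = 0L)
}

adam_step <- function(params, grads, state, lr) {
  state$t <- state$t + 1L
  bc1 <- 1 - ADAM_BETA1^state$t
  bc2 <- 1 - ADAM_BETA2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- ADAM_BETA1 * state$m[[nm]] + (1 - ADAM_BETA1) * g
    state$v[[nm]] <- ADAM_BETA2 * state$v[[nm]] + (1 - ADAM_BETA2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + ADAM_EPS)
  }
  list(params = params, state = state)
}

stack_patches <- function(ds, idx, field) {
  d1 <- dim(ds[[idx[1]]][[field]])
  out <- array(0, c(d1[1], d1[2], 1L, length(idx)))
  for (j in seq_along(idx)) out[, , 1L, j] <- ds[[idx[j]]][[field]]
  out
}

# Micro-averaged epoch metrics: confusion counts pooled over all pixels of
# all patches (matching the pixel-sum form of the Dice definition).
eval_dataset <- function(net, ds, batch_size, threshold = 0.5) {
  inter <- 0; psum <- 0; gsum <- 0; tp <- 0; loss <- 0; npx <- 0
  idx <- seq_along(ds)
  for (b in split(idx, ceiling(seq_along(idx) / batch_size))) {
    x <- stack_patches(ds, b, "x")
    g <- stack_patches(ds, b, "y")
    p <- unet_forward(net, x, train = FALSE)$p
    eps <- .Machine$double.eps
    pc <- pmin(pmax(p, eps), 1 - eps)
    loss <- loss - sum(g * log(pc) + (1 - g) * log(1 - pc))
    npx <- npx + length(p)
    pb <- p >= threshold
    inter <- inter + sum(pb & g == 1)
    psum <- psum + sum(pb)
    gsum <- gsum + sum(g)
  }
  dice <- if (psum + gsum == 0) 1 else 2 * inter / (psum + gsum)
  list(loss = loss / npx, dice = dice,
       precision = if (psum == 0) 1 else inter / psum,
       recall = if (gsum == 0) 1 else inter / gsum)
}

#' Fit the network on a patch dataset
#'
#' Minibatch Adam on the mean binary cross-entropy, recording train/val
#' loss, Dice, precision and recall per epoch (Dice monitored at a 0.5
#' binarization during training). The weights returned are those of the
#' best epoch by validation Dice (checkpoint-on-improve), not necessarily
#' the final epoch.
#'
#' @param net a `unet_model`.
#' @param train,val non-empty patch-pair lists from [build_dataset()] /
#'   [split_dataset()].
#' @param cfg a [train_config()].
#' @param verbose print one line per epoch.
#' @return `list(net, history)`; `history` is a `train_history` data.frame
#'   with attribute `best_epoch` (1-based).
#' @export
fit <- function(net, train, val, cfg = train_config(), verbose = FALSE) {
  if (length(train) == 0L || length(val) == 0L)
    stop("training and validation sets must be non-empty", call. = FALSE)
  bs <- cfg$batch_size
  if (bs > length(train)) {
    warning("batch size clipped to dataset size (", length(train), ")", call. = FALSE)
    bs <- length(train)
  }
  opt <- adam_init(net$params)
  hist <- list()
  best <- list(epoch = NA_integer_, dice = -Inf, params = net$params, stats = net$stats)
  since_improve <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    perm <- with_seed(cfg$seed + epoch, sample(seq_along(train)))
    # training metrics are aggregated from the minibatch passes themselves
    # (mid-epoch weights), avoiding a second sweep over the training set
    tr_loss <- 0; tr_n <- 0; tr_inter <- 0; tr_psum <- 0; tr_gsum <- 0
    for (b in split(perm, ceiling(seq_along(perm) / bs))) {
      x <- stack_patches(train, b, "x")
      g <- stack_patches(train, b, "y")
      fw <- unet_forward(net, x, train = TRUE)
      net$stats <- fw$stats
      eps <- .Machine$double.eps
      pc <- pmin(pmax(fw$p, eps), 1 - eps)
      tr_loss <- tr_loss - sum(g * log(pc) + (1 - g) * log(1 - pc))
      tr_n <- tr_n + length(pc)
      pb <- fw$p >= 0.5
      tr_inter <- tr_inter + sum(pb & g == 1)
      tr_psum <- tr_psum + sum(pb)
      tr_gsum <- tr_gsum + sum(g)
      dlogits <- (fw$p - g) / length(fw$p)
      grads <- unet_backward(net, fw$cache, dlogits)
      st <- adam_step(net$params, grads, opt, cfg$learning_rate)
      net$params <- st$params
      opt <- st$state
    }
    trm <- list(loss = tr_loss / tr_n,
                dice = if (tr_psum + tr_gsum == 0) 1 else 2 * tr_inter / (tr_psum + tr_gsum))
    vam <- eval_dataset(net, val, max(bs, 8L))
    hist[[epoch]] <- data.frame(
      epoch = epoch, train_loss = trm$loss, val_loss = vam$loss,
      train_dice = trm$dice, val_dice = vam$dice,
      precision = vam$precision, recall = vam$recall)
    if (verbose)
      message(sprintf("epoch %3d  train loss %.4f dice %.4f | val loss %.4f dice %.4f",
                      epoch, trm$loss, trm$dice, vam$loss, vam$dice))
    if (vam$dice > best$dice) {
      best <- list(epoch = epoch, dice = vam$dice, params = net$params, stats = net$stats)
      since_improve <- 0L
    } else {
      since_improve <- since_improve + 1L
      if (since_improve >= cfg$patience) break
    }
  }
  net$params <- best$params
  net$stats <- best$stats
  history <- do.call(rbind, hist)
  class(history) <- c("train_history", class(history))
  attr(history, "best_epoch") <- best$epoch
  list(net = net, history = history)
}

#' Best epoch of a training history
#'
#' Argmax of the validation Dice; ties broken by the earliest epoch.
#'
#' @param h a `train_history` data.frame (needs a `val_dice` column).
#' @return 1-based epoch index.
#' @export
select_best <- function(h) {
  if (is.null(h) || nrow(h) == 0L) stop("empty training history", call. = FALSE)
  which.max(h$val_dice)
}

#' Write a training history as CSV
#' @param h a `train_history`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_history <- function(h, path) {
  write.csv(as.data.frame(h), path, row.names = FALSE)
  invisible(path)
}
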