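# Forward and backward passes of the U-Net, orchestrating the compiled
# conv / transpose-conv / max-pool kernels. Activations are [H, W, C, N]
# arrays; batch norm pools statistics over H, W and N per channel.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1  # running <- (1 - mom) * running + mom * batch

sigmoid <- function(x) 1 / (1 + exp(-x))

bn_fwd <- function(x, gamma, beta, rmean, rvar, train) {
  if (train) {
    mom <- nn_bn_moments(x)
    mu <- mom$mean; va <- mom$var
    rmean <- (1 - BN_MOMENTUM) * rmean + BN_MOMENTUM * mu
    rvar <- (1 - BN_MOMENTUM) * rvar + BN_MOMENTUM * va
  } else {
    mu <- rmean; va <- rvar
  }
  # the normalized activations are only needed for the backward pass
  r <- nn_bn_fwd(x, gamma, beta, mu, va, BN_EPS, want_xhat = train)
  list(y = r$y, xhat = r$xhat, invstd = 1 / sqrt(va + BN_EPS),
       rmean = rmean, rvar = rvar)
}

bn_bwd <- function(dy, xhat, invstd, gamma) {
  r <- nn_bn_bwd(dy, xhat, invstd, gamma)
  list(dx = r$dx, dgamma = r$dgamma, dbeta = r$dbeta)
}

# conv -> [bn] -> relu -> conv -> [bn] -> relu
block_fwd <- function(net, prefix, x, train, cache, stats) {
  p <- net$params
  use_bn <- net$spec$batch_norm
  h <- nn_conv_fwd(x, p[[paste0(prefix, "_conv_a_w")]], p[[paste0(prefix, "_conv_a_b")]])
  if (use_bn) {
    nb <- paste0(prefix, "_bn_a")
    r <- bn_fwd(h, p[[paste0(nb, "_gamma")]], p[[paste0(nb, "_beta")]],
                stats[[paste0(nb, "_mean")]], stats[[paste0(nb, "_var")]], train)
    h <- r$y
    if (train) {
      stats[[paste0(nb, "_mean")]] <- r$rmean; stats[[paste0(nb, "_var")]] <- r$rvar
      cache[[paste0(nb, "_xhat")]] <- r$xhat; cache[[paste0(nb, "_invstd")]] <- r$invstd
    }
  }
  h1 <- nn_relu(h)
  h <- nn_conv_fwd(h1, p[[paste0(prefix, "_conv_b_w")]], p[[paste0(prefix, "_conv_b_b")]])
  if (use_bn) {
    nb <- paste0(prefix, "_bn_b")
    r <- bn_fwd(h, p[[paste0(nb, "_gamma")]], p[[paste0(nb, "_beta")]],
                stats[[paste0(nb, "_mean")]], stats[[paste0(nb, "_var")]], train)
    h <- r$y
    if (train) {
      stats[[paste0(nb, "_mean")]] <- r$rmean; stats[[paste0(nb, "_var")]] <- r$rvar
      cache[[paste0(nb, "_xhat")]] <- r$xhat; cache[[paste0(nb, "_invstd")]] <- r$invstd
    }
  }
  out <- nn_relu(h)
  if (train) {
    cache[[paste0(prefix, "_in")]] <- x
    cache[[paste0(prefix, "_h1")]] <- h1
    cache[[paste0(prefix, "_out")]] <- out
  }
  list(y = out, cache = cache, stats = stats)
}

block_bwd <- function(net, prefix, dy, cache, grads, need_dx = TRUE) {
  p <- net$params
  use_bn <- net$spec$batch_norm
  out <- cache[[paste0(prefix, "_out")]]
  h1 <- cache[[paste0(prefix, "_h1")]]
  x <- cache[[paste0(prefix, "_in")]]
  dy <- nn_relu_bwd(dy, out)
  if (use_bn) {
    nb <- paste0(prefix, "_bn_b")
    r <- bn_bwd(dy, cache[[paste0(nb, "_xhat")]], cache[[paste0(nb, "_invstd")]],
                p[[paste0(nb, "_gamma")]])
    grads[[paste0(nb, "_gamma")]] <- r$dgamma; grads[[paste0(nb, "_beta")]] <- r$dbeta
    dy <- r$dx
  }
  cb <- nn_conv_bwd(h1, p[[paste0(prefix, "_conv_b_w")]], dy)
  grads[[paste0(prefix, "_conv_b_w")]] <- cb$dw; grads[[paste0(prefix, "_conv_b_b")]] <- cb$db
  dy <- nn_relu_bwd(cb$dx, h1)
  if (use_bn) {
    nb <- paste0(prefix, "_bn_a")
    r <- bn_bwd(dy, cache[[paste0(nb, "_xhat")]], cache[[paste0(nb, "_invstd")]],
                p[[paste0(nb, "_gamma")]])
    grads[[paste0(nb, "_gamma")]] <- r$dgamma; grads[[paste0(nb, "_beta")]] <- r$dbeta
    dy <- r$dx
  }
  ca <- nn_conv_bwd(x, p[[paste0(prefix, "_conv_a_w")]], dy, need_dx = need_dx)
  grads[[paste0(prefix, "_conv_a_w")]] <- ca$dw; grads[[paste0(prefix, "_conv_a_b")]] <- ca$db
  list(dx = if (need_dx) ca$dx else NULL, grads = grads)
}

concat_channels <- function(a, b) nn_concat(a, b)

#' Forward pass of the network
#'
#' @param net a `unet_model` from [build_model()].
#' @param x input activations, `[H, W, 1, N]` array with values in `[0, 1]`
#'   (a single `H x W` matrix is promoted automatically).
#' @param train use batch statistics and keep the cache needed for a
#'   backward pass; otherwise inference mode with stored statistics.
#' @return `list(p, cache, stats)` where `p` is the `[H, W, 1, N]` array of
#'   per-pixel probabilities in `[0, 1]`.
#' @export
unet_forward <- function(net, x, train = FALSE) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L, 1L))
  stopifnot(length(dim(x)) == 4L)
  if (dim(x)[1] %% 2L^net$spec$depth != 0L || dim(x)[2] %% 2L^net$spec$depth != 0L)
    stop("input spatial size must be divisible by 2^depth", call. = FALSE)
  p <- net$params
  d <- net$spec$depth
  cache <- list(); stats <- net$stats
  skips <- vector("list", d)
  cur <- x
  for (i in seq_len(d)) {
    r <- block_fwd(net, sprintf("enc%d", i), cur, train, cache, stats)
    cache <- r$cache; stats <- r$stats
    skips[[i]] <- r$y
    mp <- nn_maxpool_fwd(r$y)
    if (train) {
      cache[[sprintf("pool%d_idx", i)]] <- mp$idx
      cache[[sprintf("pool%d_dim", i)]] <- dim(r$y)
    }
    cur <- mp$y
  }
  r <- block_fwd(net, "bridge", cur, train, cache, stats)
  cache <- r$cache; stats <- r$stats
  cur <- r$y
  for (i in rev(seq_len(d))) {
    up <- nn_tconv_fwd(cur, p[[sprintf("dec%d_tconv_w", i)]], p[[sprintf("dec%d_tconv_b", i)]])
    if (train) cache[[sprintf("dec%d_tconv_in", i)]] <- cur
    z <- concat_channels(up, skips[[i]])
    skips[i] <- list(NULL)
    r <- block_fwd(net, sprintf("dec%d", i), z, train, cache, stats)
    cache <- r$cache; stats <- r$stats
    cur <- r$y
  }
  logits <- nn_conv_fwd(cur, p$head_conv_w, p$head_conv_b)
  out <- sigmoid(logits)
  if (train) cache$head_in <- cur else cache <- NULL
  list(p = out, cache = cache, stats = stats)
}

# Backward pass from the gradient w.r.t. the pre-sigmoid logits.
# Unwinds head -> dec1..dec_d (collecting skip gradients) -> bridge ->
# enc_d..enc1 (adding each stored skip gradient after the un-pooling).
unet_backward <- function(net, cache, dlogits) {
  p <- net$params
  d <- net$spec$depth
  grads <- list()
  hb <- nn_conv_bwd(cache$head_in, p$head_conv_w, dlogits)
  grads$head_conv_w <- hb$dw; grads$head_conv_b <- hb$db
  dy <- hb$dx
  dskips <- vector("list", d)
  for (i in seq_len(d)) {
    r <- block_bwd(net, sprintf("dec%d", i), dy, cache, grads)
    grads <- r$grads
    dz <- r$dx
    f_up <- dim(p[[sprintf("dec%d_tconv_w", i)]])[3]  # upsampled channel count
    sp <- nn_split(dz, f_up)
    dup <- sp$a
    dskips[[i]] <- sp$b
    tb <- nn_tconv_bwd(cache[[sprintf("dec%d_tconv_in", i)]],
                       p[[sprintf("dec%d_tconv_w", i)]], dup)
    grads[[sprintf("dec%d_tconv_w", i)]] <- tb$dw
    grads[[sprintf("dec%d_tconv_b", i)]] <- tb$db
    dy <- tb$dx
  }
  r <- block_bwd(net, "bridge", dy, cache, grads)
  grads <- r$grads
  dy <- r$dx
  for (i in rev(seq_len(d))) {
    pdim <- cache[[sprintf("pool%d_dim", i)]]
    dpool <- nn_maxpool_bwd(cache[[sprintf("pool%d_idx", i)]], dy, pdim[1], pdim[2])
    # the input-image gradient of the first encoder block is never used
    r <- block_bwd(net, sprintf("enc%d", i), dpool + dskips[[i]], cache, grads,
                   need_dx = i > 1L)
    grads <- r$grads
    dy <- r$dx
  }
  grads
}
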