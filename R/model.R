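#' Architecture description for the segmentation network
#'
#' The network is a U-Net encoder-decoder: `depth` encoder blocks of two
#' (conv -> batch norm -> ReLU) layers each followed by 2x2 max pooling, a
#' bridge block of the same form at the deepest resolution with
#' `2 * filters[depth]` channels, and a mirrored decoder whose stages
#' upsample with 3x3 stride-2 transpose convolutions and concatenate the
#' matching encoder output (skip connection) before two further conv layers.
#' A 1x1 convolution with sigmoid activation produces the per-pixel root
#' probability, so output spatial size equals input size.
#'
#' @param input_size input patch side in px; must be divisible by `2^depth`.
#' @param depth number of encoder blocks.
#' @param filters channel counts per encoder level; bridge gets `2 * tail`.
#' @param conv_kernel odd conv kernel size, one value or one per level.
#' @param transpose_kernel transpose-conv kernel (fixed 3).
#' @param transpose_stride transpose-conv stride (fixed 2).
#' @param batch_norm use batch normalization after every conv (default TRUE).
#' @param resize_input if TRUE the segmenter resizes whole images to
#'   `input_size` bilinearly instead of tiling (the full-image variant).
#' @return A `model_spec` object.
#' @examples
#' model_spec()                    # the 256-px patch preset
#' faria_preset("faria1024")       # the full-image variant
#' @export
model_spec <- function(input_size = 256L, depth = 3L, filters = c(16L, 32L, 64L),
                       conv_kernel = 7L, transpose_kernel = 3L, transpose_stride = 2L,
                       batch_norm = TRUE, resize_input = FALSE) {
  depth <- as.integer(depth)
  filters <- as.integer(filters)
  if (length(filters) != depth) stop("length(filters) must equal depth", call. = FALSE)
  if (input_size %% 2L^depth != 0L)
    stop("input_size must be divisible by 2^depth", call. = FALSE)
  kern <- as.integer(conv_kernel)
  if (length(kern) == 1L) kern <- rep(kern, depth)
  if (length(kern) != depth || any(kern %% 2L == 0L))
    stop("conv_kernel must be odd, one value or one per level", call. = FALSE)
  if (transpose_kernel != 3L || transpose_stride != 2L)
    stop("only the 3x3 stride-2 transpose convolution is supported", call. = FALSE)
  structure(list(
    input_size = as.integer(input_size), depth = depth, filters = filters,
    bridge = 2L * filters[depth], conv_kernel = kern,
    transpose_kernel = 3L, transpose_stride = 2L,
    padding_mode = "zeros", batch_norm = isTRUE(batch_norm),
    dropout = FALSE, resize_input = isTRUE(resize_input)
  ), class = "model_spec")
}

#' Named architecture presets
#'
#' `"faria256"`: 256-px patches, depth 3, filters 16/32/64 with a 128-channel
#' bridge at 32x32, 7x7 kernels; inference tiles the image.
#' `"faria1024"`: whole image resized to 1024x1024, one extra encoder/decoder
#' stage with 5x5 kernels prepended (filters 8/16/32/64, bridge 128 at 64x64).
#'
#' @param name preset name.
#' @param filter_scale optional multiplier (< 1 shrinks every channel count;
#'   useful for small-scale experiments).
#' @return A [model_spec()].
#' @export
faria_preset <- function(name = c("faria256", "faria1024"), filter_scale = 1) {
  name <- match.arg(name)
  sc <- function(f) pmax(1L, as.integer(round(f * filter_scale)))
  if (name == "faria256") {
    model_spec(256L, 3L, sc(c(16L, 32L, 64L)), conv_kernel = 7L)
  } else {
    model_spec(1024L, 4L, sc(c(8L, 16L, 32L, 64L)), conv_kernel = c(5L, 7L, 7L, 7L),
               resize_input = TRUE)
  }
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec input %d, depth %d, filters %s + bridge %d, kernels %s%s>\n",
              x$input_size, x$depth, paste(x$filters, collapse = "/"), x$bridge,
              paste(x$conv_kernel, collapse = "/"),
              if (x$resize_input) ", resize-input" else ""))
  invisible(x)
}

# Enumerate all parameterized layers with their shapes.
spec_layers <- function(spec) {
  d <- spec$depth; f <- spec$filters; B <- spec$bridge; k <- spec$conv_kernel
  L <- list()
  add_conv <- function(name, k, cin, cout) L[[name]] <<- list(type = "conv", k = k, cin = cin, cout = cout)
  add_bn <- function(name, c) if (spec$batch_norm) L[[name]] <<- list(type = "bn", c = c)
  for (i in seq_len(d)) {
    cin <- if (i == 1L) 1L else f[i - 1L]
    add_conv(sprintf("enc%d_conv_a", i), k[i], cin, f[i]); add_bn(sprintf("enc%d_bn_a", i), f[i])
    add_conv(sprintf("enc%d_conv_b", i), k[i], f[i], f[i]); add_bn(sprintf("enc%d_bn_b", i), f[i])
  }
  add_conv("bridge_conv_a", k[d], f[d], B); add_bn("bridge_bn_a", B)
  add_conv("bridge_conv_b", k[d], B, B); add_bn("bridge_bn_b", B)
  for (i in rev(seq_len(d))) {
    cin <- if (i == d) B else f[i + 1L]
    L[[sprintf("dec%d_tconv", i)]] <- list(type = "tconv", k = 3L, cin = cin, cout = f[i])
    add_conv(sprintf("dec%d_conv_a", i), k[i], 2L * f[i], f[i]); add_bn(sprintf("dec%d_bn_a", i), f[i])
    add_conv(sprintf("dec%d_conv_b", i), k[i], f[i], f[i]); add_bn(sprintf("dec%d_bn_b", i), f[i])
  }
  add_conv("head_conv", 1L, f[1L], 1L)
  L
}

#' Trainable parameter count of an architecture
#'
#' Pure arithmetic over the layer shapes: `k^2 * cin * cout + cout` per
#' (transpose) convolution plus `2 * channels` per batch-norm layer.
#'
#' @param spec a [model_spec()].
#' @return Integer parameter count.
#' @export
parameter_count <- function(spec) {
  sum(vapply(spec_layers(spec), function(l) {
    switch(l$type,
           conv = , tconv = l$k^2 * l$cin * l$cout + l$cout,
           bn = 2 * l$c)
  }, numeric(1)))
}

#' Instantiate a network from an architecture spec
#'
#' Allocates all weights (zero until [init_weights()] is applied, which
#' [build_model()] does by default) and the batch-norm running statistics.
#'
#' @param spec a [model_spec()].
#' @param seed RNG seed for weight initialization; `NULL` leaves weights zero.
#' @return A `unet_model` object.
#' @export
build_model <- function(spec, seed = 1L) {
  layers <- spec_layers(spec)
  params <- list()
  stats <- list()
  for (nm in names(layers)) {
    l <- layers[[nm]]
    if (l$type == "conv") {
      params[[paste0(nm, "_w")]] <- array(0, c(l$k, l$k, l$cin, l$cout))
      params[[paste0(nm, "_b")]] <- numeric(l$cout)
    } else if (l$type == "tconv") {
      params[[paste0(nm, "_w")]] <- array(0, c(l$k, l$k, l$cout, l$cin))
      params[[paste0(nm, "_b")]] <- numeric(l$cout)
    } else {
      params[[paste0(nm, "_gamma")]] <- rep(1, l$c)
      params[[paste0(nm, "_beta")]] <- numeric(l$c)
      stats[[paste0(nm, "_mean")]] <- numeric(l$c)
      stats[[paste0(nm, "_var")]] <- rep(1, l$c)
    }
  }
  net <- structure(list(spec = spec, params = params, stats = stats,
                        parameter_count = parameter_count(spec),
                        model_id = sprintf("unet-d%d-f%s", spec$depth,
                                           paste(spec$filters, collapse = "."))),
                   class = "unet_model")
  if (!is.null(seed)) net <- init_weights(net, seed) else net
}

#' Randomly initialize network weights
#'
#' All convolution and transpose-convolution weights are drawn i.i.d.
#' Normal(mean 0, sd 0.05); biases and batch-norm shifts are zero, batch-norm
#' scales one. Deterministic under `seed`.
#'
#' @param net a `unet_model`.
#' @param seed integer seed.
#' @return The re-initialized model.
#' @export
init_weights <- function(net, seed = 1L) {
  with_seed(seed, {
    for (nm in names(net$params)) {
      if (grepl("_w$", nm)) {
        d <- dim(net$params[[nm]])
        net$params[[nm]] <- array(rnorm(prod(d), 0, 0.05), d)
      } else if (grepl("_b$|_beta$", nm)) {
        net$params[[nm]][] <- 0
      } else if (grepl("_gamma$", nm)) {
        net$params[[nm]][] <- 1
      }
    }
  })
  for (nm in names(net$stats)) {
    net$stats[[nm]][] <- if (grepl("_var$", nm)) 1 else 0
  }
  net
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf("<unet_model %s, input %d, %d parameters>\n",
              x$model_id, x$spec$input_size, x$parameter_count))
  invisible(x)
}

#' Save / load network weights
#'
#' The container stores the architecture spec alongside the weights, so
#' loading reconstructs the model without user input; loading into an
#' explicitly supplied, mismatching spec is rejected.
#'
#' @param net a `unet_model`.
#' @param path output file path.
#' @return `save_weights`: `path` invisibly; `load_weights`: the model.
#' @export
save_weights <- function(net, path) {
  payload <- list(format = "rhizoseg-unet-1",
                  spec = unclass(net$spec),
                  params = net$params, stats = net$stats)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_weights
#' @param spec optional [model_spec()] the weights must match.
#' @export
load_weights <- function(path, spec = NULL) {
  payload <- readRDS(path)
  if (!identical(payload$format, "rhizoseg-unet-1"))
    stop("not a recognized weights file", call. = FALSE)
  file_spec <- do.call(model_spec, payload$spec[c("input_size", "depth", "filters",
                                                  "conv_kernel", "batch_norm", "resize_input")])
  if (!is.null(spec) && !identical(unclass(spec), unclass(file_spec)))
    stop("weights file does not match the requested architecture", call. = FALSE)
  net <- build_model(file_spec, seed = NULL)
  stopifnot(identical(names(net$params), names(payload$params)))
  net$params <- payload$params
  net$stats <- payload$stats
  net
}
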