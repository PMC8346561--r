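# Shared fixtures, built in code at test time.

# A tiny network (32-px input, depth 2) for fast structural tests.
tiny_spec <- function(input_size = 32L, resize_input = FALSE) {
  model_spec(input_size = input_size, depth = 2L, filters = c(2L, 3L),
             conv_kernel = 3L, resize_input = resize_input)
}

tiny_net <- function(seed = 3L, ...) build_model(tiny_spec(...), seed = seed)

random_mask <- function(h, w, p = 0.3) {
  binary_mask(matrix(rbinom(h * w, 1L, p), h, w))
}

random_gray <- function(h, w, bit_depth = 8L) {
  gray_image(matrix(sample(0:(2^bit_depth - 1), h * w, replace = TRUE), h, w), bit_depth)
}

# A horizontal bar mask: `width` px tall, `len` px long, centered-ish.
bar_mask <- function(h, w, row0, width, col0, len) {
  m <- matrix(0L, h, w)
  m[row0:(row0 + width - 1L), col0:(col0 + len - 1L)] <- 1L
  binary_mask(m)
}

# Mini training set: four 32x32 patch pairs with a bright vertical band.
mini_patches <- function(n = 4L, size = 32L, seed = 5L) {
  rhizoseg:::with_seed(seed, lapply(seq_len(n), function(i) {
    y <- matrix(0L, size, size)
    c0 <- sample(seq_len(size - 6L), 1L)
    y[, c0:(c0 + 2L)] <- 1L
    x <- matrix(runif(size^2, 0, 0.4), size)
    x[y == 1L] <- x[y == 1L] + 0.5
    list(x = pmin(x, 1), y = y, source_id = paste0("p", i),
         row_index = 0L, col_index = 0L)
  }))
}
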