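test_that("spec validation enforces the architecture invariants", {
  expect_error(model_spec(input_size = 100L), "divisible")
  expect_error(model_spec(filters = c(16L, 32L)), "length")
  expect_error(model_spec(conv_kernel = 4L), "odd")
  s <- model_spec()
  expect_equal(s$bridge, 128L)
  expect_equal(s$filters, c(16L, 32L, 64L))
  s1024 <- faria_preset("faria1024")
  expect_equal(s1024$depth, 4L)
  expect_equal(s1024$conv_kernel, c(5L, 7L, 7L, 7L))
  expect_true(s1024$resize_input)
  expect_equal(s1024$bridge, 128L)
})

test_that("parameter count matches independent layer-wise arithmetic", {
  # oracle: sum k^2*cin*cout + cout over convs, 9*cin*cout + cout over
  # transpose convs, 2c per batch norm, for the 256-px preset
  conv <- function(k, ci, co) k^2 * ci * co + co
  convs <- conv(7, 1, 16) + conv(7, 16, 16) +      # encoder 1
    conv(7, 16, 32) + conv(7, 32, 32) +            # encoder 2
    conv(7, 32, 64) + conv(7, 64, 64) +            # encoder 3
    conv(7, 64, 128) + conv(7, 128, 128) +         # bridge
    conv(3, 128, 64) + conv(7, 128, 64) + conv(7, 64, 64) +  # decoder 3
    conv(3, 64, 32) + conv(7, 64, 32) + conv(7, 32, 32) +    # decoder 2
    conv(3, 32, 16) + conv(7, 32, 16) + conv(7, 16, 16) +    # decoder 1
    conv(1, 16, 1)                                  # head
  bn <- 2 * 2 * (16 + 32 + 64 + 128 + 64 + 32 + 16)
  expect_equal(parameter_count(faria_preset("faria256")), convs + bn)
  expect_equal(parameter_count(faria_preset("faria256")), 2483153)
})

test_that("weight initialization is Normal(0, 0.05), seeded, biases zero", {
  net <- tiny_net(seed = 10L)
  w <- unlist(net$params[grepl("_w$", names(net$params))])
  se <- 0.05 / sqrt(2 * length(w))  # SE of the sd estimate
  expect_lt(abs(mean(w)), 3 * 0.05 / sqrt(length(w)))
  expect_lt(abs(sd(w) - 0.05), 3 * se)
  expect_true(all(unlist(net$params[grepl("_b$|_beta$", names(net$params))]) == 0))
  net2 <- tiny_net(seed = 10L)
  expect_identical(net$params, net2$params)
  expect_false(identical(net$params, tiny_net(seed = 11L)$params))
})

test_that("forward pass preserves shape and stays in [0, 1]", {
  net <- tiny_net()
  x <- array(rnorm(32 * 32 * 2, sd = 5), c(32, 32, 1, 2))  # arbitrary reals
  p <- unet_forward(net, x)$p
  expect_equal(dim(p), c(32L, 32L, 1L, 2L))
  expect_true(all(p >= 0 & p <= 1))
  # all-zero input still yields a valid probability field
  p0 <- unet_forward(net, matrix(0, 32, 32))$p
  expect_true(all(p0 >= 0 & p0 <= 1))
})

test_that("the scaled-down deep variant (5-px first kernel) preserves shape", {
  # same topology as the full-image preset: depth 4, 5/7/7/7 kernels
  spec <- model_spec(input_size = 64L, depth = 4L, filters = c(2L, 3L, 4L, 5L),
                     conv_kernel = c(5L, 7L, 7L, 7L))
  net <- build_model(spec, seed = 2L)
  p <- unet_forward(net, matrix(runif(64 * 64), 64, 64))$p
  expect_equal(dim(p), c(64L, 64L, 1L, 1L))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("the 256-px preset reproduces the reference feature-map schedule", {
  net <- build_model(faria_preset("faria256"), seed = 1L)
  x <- array(runif(256 * 256), c(256, 256, 1, 1))
  fw <- unet_forward(net, x, train = TRUE)
  sched <- lapply(fw$cache, dim)
  # encoder block outputs (Table of encoder shapes)
  expect_equal(sched$enc1_out[1:3], c(256L, 256L, 16L))
  expect_equal(sched$enc2_out[1:3], c(128L, 128L, 32L))
  expect_equal(sched$enc3_out[1:3], c(64L, 64L, 64L))
  # 128-channel bridge at 32 x 32
  expect_equal(sched$bridge_out[1:3], c(32L, 32L, 128L))
  # decoder outputs mirror the encoder
  expect_equal(sched$dec3_out[1:3], c(64L, 64L, 64L))
  expect_equal(sched$dec2_out[1:3], c(128L, 128L, 32L))
  expect_equal(sched$dec1_out[1:3], c(256L, 256L, 16L))
  expect_equal(dim(fw$p)[1:2], c(256L, 256L))
})

test_that("weight save/load round-trips and rejects mismatched specs", {
  td <- withr::local_tempdir()
  net <- tiny_net(seed = 4L)
  x <- array(runif(32 * 32), c(32, 32, 1, 1))
  p1 <- unet_forward(net, x)$p
  f <- file.path(td, "w.rds")
  save_weights(net, f)
  net2 <- load_weights(f)  # spec reconstructed from the file metadata
  expect_identical(unclass(net2$spec), unclass(net$spec))
  expect_identical(unet_forward(net2, x)$p, p1)
  expect_error(load_weights(f, spec = model_spec(input_size = 64L, depth = 2L,
                                                 filters = c(2L, 3L),
                                                 conv_kernel = 3L)),
               "does not match")
  saveRDS(list(format = "other"), f)
  expect_error(load_weights(f), "not a recognized")
})
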