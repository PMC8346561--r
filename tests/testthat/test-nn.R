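# Differentiation correctness of the native network implementation.
# The stride-1 convolutions accumulate in single precision, so they are
# checked against double-precision nested-loop oracles at float tolerance,
# and the end-to-end finite-difference check uses a step and tolerance
# sized to that rounding floor.

conv_oracle_fwd <- function(x, w, b) {
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]
  k <- dim(w)[1]; Cout <- dim(w)[4]; pad <- (k - 1L) / 2L
  y <- array(0, c(H, W, Cout, 1L))
  for (co in 1:Cout) for (r in 1:H) for (cc in 1:W) {
    acc <- b[co]
    for (ci in 1:Cin) for (ki in 1:k) for (kj in 1:k) {
      rr <- r + ki - 1L - pad; ww <- cc + kj - 1L - pad
      if (rr >= 1 && rr <= H && ww >= 1 && ww <= W)
        acc <- acc + x[rr, ww, ci, 1] * w[ki, kj, ci, co]
    }
    y[r, cc, co, 1] <- acc
  }
  y
}

test_that("convolution forward matches a direct nested-loop oracle", {
  set.seed(12)
  x <- array(rnorm(6 * 5 * 2), c(6, 5, 2, 1))
  w <- array(rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3))
  b <- rnorm(3)
  y <- rhizoseg:::nn_conv_fwd(x, w, b)
  expect_equal(y, conv_oracle_fwd(x, w, b), tolerance = 1e-5)
})

test_that("convolution backward matches the adjoint oracle", {
  set.seed(18)
  H <- 5L; W <- 6L; Cin <- 2L; Cout <- 2L; k <- 3L; pad <- 1L
  x <- array(rnorm(H * W * Cin), c(H, W, Cin, 1L))
  w <- array(rnorm(k * k * Cin * Cout), c(k, k, Cin, Cout))
  dy <- array(rnorm(H * W * Cout), c(H, W, Cout, 1L))
  got <- rhizoseg:::nn_conv_bwd(x, w, dy)
  # oracles from the definition y[r,c,co] = sum x[r+ki-1-pad, ...] w[ki,kj,ci,co]
  dw <- array(0, dim(w)); dx <- array(0, dim(x)); db <- numeric(Cout)
  for (co in 1:Cout) {
    db[co] <- sum(dy[, , co, 1])
    for (r in 1:H) for (cc in 1:W) for (ci in 1:Cin) for (ki in 1:k) for (kj in 1:k) {
      rr <- r + ki - 1L - pad; ww <- cc + kj - 1L - pad
      if (rr >= 1 && rr <= H && ww >= 1 && ww <= W) {
        dw[ki, kj, ci, co] <- dw[ki, kj, ci, co] + x[rr, ww, ci, 1] * dy[r, cc, co, 1]
        dx[rr, ww, ci, 1] <- dx[rr, ww, ci, 1] + w[ki, kj, ci, co] * dy[r, cc, co, 1]
      }
    }
  }
  expect_equal(got$dw, dw, tolerance = 1e-5)
  expect_equal(got$dx, dx, tolerance = 1e-5)
  expect_equal(as.numeric(got$db), db, tolerance = 1e-10)
})

test_that("analytic end-to-end gradients agree with finite differences", {
  set.seed(7)
  spec <- model_spec(input_size = 8L, depth = 2L, filters = c(2L, 3L), conv_kernel = 3L)
  net <- build_model(spec, seed = 3L)
  x <- array(runif(8 * 8 * 2), c(8, 8, 1, 2))
  g <- array(rbinom(8 * 8 * 2, 1, 0.3), c(8, 8, 1, 2))
  loss_fn <- function(net) {
    p <- rhizoseg:::unet_forward(net, x, train = TRUE)$p
    bce_loss(p, g)
  }
  fw <- rhizoseg:::unet_forward(net, x, train = TRUE)
  grads <- rhizoseg:::unet_backward(net, fw$cache, (fw$p - g) / length(fw$p))
  h <- 1e-5
  for (nm in names(net$params)) {
    for (i in sample(length(net$params[[nm]]), min(2, length(net$params[[nm]])))) {
      np <- net
      np$params[[nm]][i] <- np$params[[nm]][i] + h
      lp <- loss_fn(np)
      np$params[[nm]][i] <- np$params[[nm]][i] - 2 * h
      lm <- loss_fn(np)
      num <- (lp - lm) / (2 * h)
      # absolute floor covers single-precision forward noise at this h
      expect_lt(abs(grads[[nm]][i] - num),
                0.02 * (abs(num) + abs(grads[[nm]][i])) + 2e-5,
                label = paste("gradient of", nm))
    }
  }
  # aggregate directional derivative along random parameter directions
  nm_ <- names(net$params)
  for (k in 1:3) {
    set.seed(k)
    v <- lapply(net$params, function(p) { p[] <- rnorm(length(p)); p })
    np <- net
    for (nm in nm_) np$params[[nm]] <- net$params[[nm]] + h * v[[nm]]
    lp <- loss_fn(np)
    for (nm in nm_) np$params[[nm]] <- net$params[[nm]] - h * v[[nm]]
    lm <- loss_fn(np)
    num <- (lp - lm) / (2 * h)
    ana <- sum(vapply(nm_, function(nm) sum(grads[[nm]] * v[[nm]]), numeric(1)))
    expect_equal(ana, num, tolerance = 0.05)
  }
})

test_that("transpose convolution doubles resolution and matches its oracle", {
  set.seed(13)
  H <- 4L; W <- 3L; Cin <- 2L; Cout <- 2L
  x <- array(rnorm(H * W * Cin), c(H, W, Cin, 1L))
  w <- array(rnorm(9 * Cout * Cin), c(3L, 3L, Cout, Cin))
  b <- rnorm(Cout)
  y <- rhizoseg:::nn_tconv_fwd(x, w, b)
  expect_equal(dim(y), c(2L * H, 2L * W, Cout, 1L))
  oracle <- array(0, c(2L * H, 2L * W, Cout, 1L))
  for (co in 1:Cout) {
    for (r in 1:H) for (cc in 1:W) for (ki in 1:3) for (kj in 1:3) {
      R <- 2L * (r - 1L) - 1L + (ki - 1L) + 1L  # 1-based output row, pad 1
      C <- 2L * (cc - 1L) - 1L + (kj - 1L) + 1L
      if (R >= 1 && R <= 2 * H && C >= 1 && C <= 2 * W) {
        for (ci in 1:Cin)
          oracle[R, C, co, 1] <- oracle[R, C, co, 1] + x[r, cc, ci, 1] * w[ki, kj, co, ci]
      }
    }
    oracle[, , co, 1] <- oracle[, , co, 1] + b[co]
  }
  expect_equal(y, oracle, tolerance = 1e-12)
})

test_that("max pooling halves resolution and routes gradients to the argmax", {
  x <- array(0, c(4, 4, 1, 1))
  x[1:4, 1:4, 1, 1] <- matrix(1:16, 4, 4)
  mp <- rhizoseg:::nn_maxpool_fwd(x)
  expect_equal(mp$y[, , 1, 1], matrix(c(6, 8, 14, 16), 2, 2))
  dy <- array(1, c(2, 2, 1, 1))
  dx <- rhizoseg:::nn_maxpool_bwd(mp$idx, dy, 4L, 4L)
  expect_equal(sum(dx), 4)
  expect_equal(which(dx != 0), c(6L, 8L, 14L, 16L))
})

test_that("inference is deterministic and independent of batch composition", {
  net <- tiny_net(seed = 6L)
  set.seed(1)
  x <- array(runif(32 * 32 * 3), c(32, 32, 1, 3))
  p1 <- unet_forward(net, x)$p
  p2 <- unet_forward(net, x)$p
  expect_identical(p1, p2)
  for (j in 1:3) {
    pj <- unet_forward(net, array(x[, , , j], c(32, 32, 1, 1)))$p
    expect_equal(pj[, , 1, 1], p1[, , 1, j], tolerance = 1e-12)
  }
})
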