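# Network building blocks against independent nested-loop oracles.

test_that("conv block matches the loop oracle and its special cases", {
  set.seed(11)
  # identity kernel passes ReLU(input) through
  x <- array(rnorm(25), c(5, 5, 1))
  w_id <- array(0, c(3, 3, 1, 1)); w_id[2, 2, 1, 1] <- 1
  expect_equal(conv_block_forward(x, w_id, 0), array(pmax(x, 0), c(5, 5, 1)),
               tolerance = 1e-12)
  # zero kernels and biases give zero output
  expect_true(all(conv_block_forward(x, array(0, c(3, 3, 1, 2)), c(0, 0)) == 0))
  # random multi-map input matches the nested-loop cross-correlation
  x2 <- array(rnorm(50), c(5, 5, 2))
  w2 <- array(rnorm(54), c(3, 3, 2, 3))
  b2 <- rnorm(3)
  expect_equal(conv_block_forward(x2, w2, b2, "linear"), loop_conv(x2, w2, b2),
               tolerance = 1e-6)
  expect_equal(conv_block_forward(x2, w2, b2),
               array(pmax(loop_conv(x2, w2, b2), 0), c(5, 5, 3)),
               tolerance = 1e-6)
  expect_error(conv_block_forward(x2, array(0, c(3, 3, 3, 1)), 0), "maps")
})

test_that("batch normalization honours its contracts and Eq oracle", {
  set.seed(12)
  # standardization contract
  x <- matrix(rnorm(5000), 1000, 5)
  y <- batchnorm_forward(x, gamma = rep(1, 5), beta = rep(0, 5))
  expect_lt(max(abs(colMeans(y))), 3 / sqrt(1000))
  expect_lt(max(abs(apply(y, 2, stats::sd) - 1)), 3 / sqrt(1000))
  # affine contract on normalized input
  y2 <- batchnorm_forward(scale(x), gamma = rep(2, 5), beta = rep(3, 5))
  expect_lt(max(abs(colMeans(y2) - 3)), 0.01)
  expect_lt(max(abs(apply(y2, 2, stats::sd) - 2)), 0.01)
  # direct formula oracle
  xs <- matrix(rnorm(60), 10, 6)
  g <- runif(6); b <- rnorm(6)
  expect_equal(batchnorm_forward(xs, g, b, eps = 1e-5),
               loop_bn(xs, g, b, 1e-5), tolerance = 1e-6)
  # inference mode uses the provided running statistics
  out <- batchnorm_forward(xs, g, b, training = FALSE,
                           run_mean = rep(0, 6), run_var = rep(1, 6))
  expect_equal(out, sweep(sweep(xs / sqrt(1 + 1e-5), 2, g, "*"), 2, b, "+"),
               tolerance = 1e-6)
  expect_error(batchnorm_forward(xs[1, , drop = FALSE], g, b), "batch size")
})

test_that("max pooling matches the exhaustive window oracle", {
  expect_equal(maxpool_forward(matrix(c(1, 3, 2, 4), 2, 2)),
               matrix(4, 1, 1))
  expect_equal(maxpool_forward(array(7, c(4, 4, 2))), array(7, c(2, 2, 2)))
  set.seed(13)
  x <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  expect_equal(maxpool_forward(x), loop_pool(x), tolerance = 1e-12)
  expect_error(maxpool_forward(array(0, c(5, 6, 1))), "even")
})

test_that("channel attention matches the scalar oracle of its equation", {
  set.seed(14)
  C <- 8; r <- 4
  M0 <- matrix(rnorm(C / r * C), C / r, C)
  M1 <- matrix(rnorm(C * C / r), C, C / r)
  # constant map: avg-pool == max-pool, so the two branches coincide
  fconst <- array(2, c(4, 4, C))
  v <- rep(2, C)
  manual <- 1 / (1 + exp(-(2 * M1 %*% pmax(M0 %*% v, 0))))
  expect_equal(channel_attention(fconst, M0, M1), as.numeric(manual),
               tolerance = 1e-9)
  # zero MLP weights give sigma(0) = 0.5
  expect_equal(channel_attention(fconst, M0 * 0, M1 * 0), rep(0.5, C))
  # random input against the loop oracle
  f <- array(rnorm(4 * 4 * C), c(4, 4, C))
  expect_equal(channel_attention(f, M0, M1), loop_channel_attention(f, M0, M1),
               tolerance = 1e-6)
  expect_error(channel_attention(f, M0[, 1:4], M1), "inconsistent")
})

test_that("spatial attention matches the scalar oracle of its equation", {
  set.seed(15)
  w7 <- array(rnorm(98), c(7, 7, 2, 1))
  f <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  expect_equal(spatial_attention(f, w7), loop_spatial_attention(f, w7),
               tolerance = 1e-6)
  # zero conv weights: uniform sigma(0) map
  expect_equal(spatial_attention(f, w7 * 0), matrix(0.5, 8, 8))
  # spatially constant feature map: away from padding edges the map is flat
  fc <- array(1, c(12, 12, 3))
  s <- spatial_attention(fc, w7)
  expect_lt(max(abs(s[4:9, 4:9] - s[6, 6])), 1e-9)
})

test_that("CBAM composes the two attentions multiplicatively and contracts", {
  set.seed(16)
  C <- 8
  params <- list(M0 = matrix(rnorm(C / 2 * C), C / 2, C),
                 M1 = matrix(rnorm(C * C / 2), C, C / 2),
                 w7 = array(rnorm(98), c(7, 7, 2, 1)), b7 = 0)
  f <- array(rnorm(6 * 6 * C), c(6, 6, C))
  out <- cbam_apply(f, params)
  # manual composition
  mc <- channel_attention(f, params$M0, params$M1)
  fc <- f * rep(mc, each = 36)
  ms <- spatial_attention(fc, params$w7, 0)
  expect_equal(out, fc * as.vector(ms), tolerance = 1e-9)
  # multiplicative: zero in, zero out; |out| <= |in| since weights < 1
  expect_true(all(cbam_apply(array(0, c(6, 6, C)), params) == 0))
  expect_true(all(abs(out) <= abs(f) + 1e-12))
  # attention forced to ~1 by construction: large positive weights saturate
  # both sigmoids, so the block reduces to the identity
  sat <- list(M0 = matrix(50, 2, C), M1 = matrix(50, C, 2),
              w7 = array(0, c(7, 7, 2, 1)), b7 = 50)
  fpos <- array(abs(rnorm(6 * 6 * C)) + 0.1, c(6, 6, C))
  expect_equal(cbam_apply(fpos, sat), fpos, tolerance = 1e-6)
})

test_that("label smoothing and the smoothed loss follow their formulas", {
  expect_identical(smooth_labels(1, 0.1), 0.9)
  expect_identical(smooth_labels(0, 0.3), 0)        # asymmetric, as specified
  expect_identical(smooth_labels(c(0, 1), 0), c(0, 1))
  expect_equal(smooth_labels(c(0, 1), 0.1, symmetric = TRUE), c(0.1, 0.9))
  expect_error(smooth_labels(1, 1), "eps")
  expect_error(smooth_labels(0.4, 0.1), "0 or 1")
  # perfect prediction drives the loss to ~0
  expect_lt(smoothed_bce(1 - 1e-9, 1), 1e-5)
  # scalar formula oracle
  expect_equal(smoothed_bce(0.9, 0.9), -(0.9 * log(0.9) + 0.1 * log(0.1)),
               tolerance = 1e-12)
  # mean reduction: duplicating a sample leaves the loss unchanged
  expect_equal(smoothed_bce(c(0.7, 0.7), c(0.9, 0.9)), smoothed_bce(0.7, 0.9))
})
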