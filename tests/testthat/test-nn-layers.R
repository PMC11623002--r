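# The convolution/pooling/normalization kernels against independent
# oracles: a direct quadruple-loop convolution in R and central finite
# differences. Kernels accumulate in single precision, so tolerances sit
# at the float level.

sf <- asNamespace("splitfed")

test_that("convolution forward matches the direct-loop oracle", {
  set.seed(42)
  x <- array(rnorm(7 * 7 * 3 * 2), c(7, 7, 3, 2))
  w <- array(rnorm(3 * 3 * 3 * 4), c(3, 3, 3, 4))
  b <- rnorm(4)
  for (stride in 1:2) {
    got <- sf$cpp_conv_fw(x, dim(x), w, dim(w), b, stride, 1L, 1L, 1L, 1L)
    want <- naive_conv(x, w, b, stride, 1, 1, 1, 1)
    expect_equal(got, want, tolerance = 1e-5)
  }
  # asymmetric ('same'-style) padding
  got <- sf$cpp_conv_fw(x, dim(x), w, dim(w), b, 2L, 0L, 1L, 0L, 1L)
  want <- naive_conv(x, w, b, 2, 0, 1, 0, 1)
  expect_equal(got, want, tolerance = 1e-5)
})

test_that("convolution gradients match finite differences", {
  set.seed(43)
  x <- array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2))
  w <- array(rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3))
  b <- rnorm(3)
  loss <- function(x2, w2, b2)
    sum(sf$cpp_conv_fw(x2, dim(x), w2, dim(w), b2, 2L, 1L, 1L, 1L, 1L)^2) / 2
  y <- sf$cpp_conv_fw(x, dim(x), w, dim(w), b, 2L, 1L, 1L, 1L, 1L)
  dx <- sf$cpp_conv_bw_data(y, dim(y), w, dim(w), 2L, 1L, 1L, 1L, 1L,
                            6L, 6L, numeric(0))
  g <- sf$cpp_conv_bw_filter(x, dim(x), y, dim(y), 3L, 2L, 1L, 1L, 1L, 1L)
  for (i in sample(length(x), 5))
    expect_equal(dx[i], fd_grad(function(v) loss(v, w, b), x, i),
                 tolerance = 1e-2)
  for (i in sample(length(w), 5))
    expect_equal(g$dw[i], fd_grad(function(v) loss(x, v, b), w, i),
                 tolerance = 1e-2)
  expect_equal(g$db[2], fd_grad(function(v) loss(x, w, v), b, 2),
               tolerance = 1e-2)
})

test_that("transposed convolution shapes and gradients are correct", {
  set.seed(44)
  # stride 2 doubles the map; stride 1 with 'same' padding preserves it
  l2 <- sf$layer_tconv(4L, 2L, 3L, stride = 2L, output_size = 8L)
  l1 <- sf$layer_tconv(4L, 3L, 1L, stride = 1L, output_size = 8L)
  x <- array(rnorm(4 * 4 * 2 * 2), c(4, 4, 2, 2))
  y <- sf$layer_forward(l2, x)
  expect_equal(dim(y), c(8L, 8L, 3L, 2L))
  expect_equal(dim(sf$layer_forward(l1, y)), c(8L, 8L, 1L, 2L))

  w0 <- l2$par$w
  loss <- function(wv) { l2$par$w <- wv; sum(sf$layer_forward(l2, x)^2) / 2 }
  y <- sf$layer_forward(l2, x)
  dx <- sf$layer_backward(l2, y)
  gw <- l2$grad$w
  l2$par$w <- w0
  for (i in sample(length(w0), 5))
    expect_equal(gw[i], fd_grad(loss, w0, i), tolerance = 1e-2)
  lossx <- function(xv) sum(sf$layer_forward(l2, xv)^2) / 2
  for (i in sample(length(x), 5))
    expect_equal(dx[i], fd_grad(lossx, x, i), tolerance = 1e-2)
})

test_that("small and generic transposed-convolution forwards agree", {
  set.seed(45)
  l <- sf$layer_tconv(4L, 2L, 5L, stride = 2L, output_size = 12L)
  x <- array(rnorm(6 * 6 * 2 * 3), c(6, 6, 2, 3))
  fast <- sf$layer_forward(l, x)
  l$cfg$small <- FALSE
  generic <- sf$layer_forward(l, x)
  expect_equal(fast, generic, tolerance = 1e-5)
})

test_that("batch norm normalizes per channel and its gradients check out", {
  set.seed(46)
  x <- array(rnorm(5 * 5 * 3 * 4, 2, 3), c(5, 5, 3, 4))
  g <- c(1.5, 0.8, 1); b <- c(0.1, -0.2, 0)
  r <- sf$cpp_bn_fw(x, dim(x), g, b, numeric(3), rep(1, 3), 1e-5, 0.1, TRUE)
  for (c in 1:3) {
    xh <- (x[, , c, ] - mean(x[, , c, ])) /
      sqrt(mean((x[, , c, ] - mean(x[, , c, ]))^2) + 1e-5)
    expect_equal(r$y[, , c, ], g[c] * xh + b[c], tolerance = 1e-5)
  }
  lossbn <- function(x2) {
    r2 <- sf$cpp_bn_fw(x2, dim(x2), g, b, numeric(3), rep(1, 3), 1e-5, 0.1,
                       TRUE)
    sum(r2$y^3) / 3
  }
  bw <- sf$cpp_bn_bw(x, r$y^2, dim(x), g, r$mean, r$var, 1e-5)
  for (i in sample(length(x), 4))
    expect_equal(bw$dx[i], fd_grad(lossbn, x, i, eps = 1e-3),
                 tolerance = 5e-2)
  # eval mode uses running statistics, not batch statistics
  re <- sf$cpp_bn_fw(x, dim(x), g, b, c(0, 0, 0), c(1, 1, 1), 1e-5, 0.1,
                     FALSE)
  expect_equal(re$y[, , 1, ], g[1] * x[, , 1, ] / sqrt(1 + 1e-5) + b[1],
               tolerance = 1e-5)
})

test_that("fused batch-norm activation equals norm followed by ReLU", {
  set.seed(47)
  x <- array(rnorm(4 * 4 * 2 * 3), c(4, 4, 2, 3))
  plain <- sf$layer_bn(2L)
  fused <- sf$layer_bn(2L, act = "relu")
  y1 <- pmax(sf$layer_forward(plain, x, TRUE), 0)
  y2 <- sf$layer_forward(fused, x, TRUE)
  expect_equal(y1, y2)
  # gradient consistency against finite differences through the fused op
  lossf <- function(x2) {
    l <- sf$layer_bn(2L, act = "relu")
    sum(sf$layer_forward(l, x2, TRUE)^2) / 2
  }
  y <- sf$layer_forward(fused, x, TRUE)
  dx <- sf$layer_backward(fused, y)
  for (i in sample(length(x), 4))
    expect_equal(dx[i], fd_grad(lossf, x, i, eps = 1e-3), tolerance = 5e-2)
})

test_that("max pooling picks window maxima and routes gradients to them", {
  set.seed(48)
  x <- array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2))
  r <- sf$cpp_maxpool_fw(x, dim(x), 3L, 2L, 1L)
  expect_equal(dim(r$y), c(3L, 3L, 2L, 2L))
  expect_equal(r$y[1, 1, 1, 1], max(x[1:2, 1:2, 1, 1]))
  expect_equal(r$y[2, 2, 2, 1], max(x[2:4, 2:4, 2, 1]))
  dy <- r$y; dy[] <- 1
  dx <- sf$cpp_maxpool_bw(dy, r$idx, dim(x))
  expect_equal(sum(dx), length(r$y))   # each output routes one unit back
})

test_that("one fused Adam step equals the reference update", {
  set.seed(49)
  p <- rnorm(20); g <- rnorm(20)
  l <- sf$new_layer("dense", par = list(w = p))
  l$grad <- list(w = g)
  opt <- sf$new_adam(lr = 1e-2)
  sf$adam_step(opt, list(l))
  m <- 0.1 * g; v <- 0.001 * g^2
  want <- p - 1e-2 * (m / 0.1) / (sqrt(v / 0.001) + 1e-8)
  expect_equal(l$par$w, want, tolerance = 1e-12)
  # a zero gradient from a fresh state leaves parameters exactly unchanged
  l2 <- sf$new_layer("dense", par = list(w = p))
  l2$grad <- list(w = g * 0)
  sf$adam_step(sf$new_adam(), list(l2))
  expect_identical(l2$par$w, p)
})
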