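# The network layers are implemented in the package (C++ for the 2D
# kernels, R for the 1D ones); every backward pass is checked against
# central-difference gradients, and the convolution forwards against naive
# nested-loop references.

test_that("2D convolution matches a nested-loop reference and its gradients", {
  set.seed(1)
  H <- 7; W <- 6; Cin <- 3; Cout <- 2; B <- 2
  x <- array(rnorm(H * W * Cin * B), c(H, W, Cin, B))
  w <- array(rnorm(3 * 3 * Cin * Cout), c(3, 3, Cin, Cout))
  b <- rnorm(Cout)
  y <- coroflow:::.cfConv2dForward(x, w, b)
  ref <- array(0, c(H, W, Cout, B))
  for (bb in 1:B) for (co in 1:Cout) for (i in 1:H) for (j in 1:W) {
    s <- b[co]
    for (ci in 1:Cin) for (ky in -1:1) for (kx in -1:1) {
      ii <- i + ky; jj <- j + kx
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
        s <- s + x[ii, jj, ci, bb] * w[ky + 2, kx + 2, ci, co]
    }
    ref[i, j, co, bb] <- s
  }
  expect_lt(max(abs(y - ref)), 1e-12)

  dy <- array(rnorm(length(y)), dim(y))
  g <- coroflow:::.cfConv2dBackward(x, w, dy)
  L <- function(x_, w_, b_) sum(coroflow:::.cfConv2dForward(x_, w_, b_) * dy)
  expect_lt(max(abs(numGrad(function(z) L(z, w, b), x) - g$dx)), 1e-7)
  expect_lt(max(abs(numGrad(function(z) L(x, z, b), w) - g$dw)), 1e-7)
  expect_lt(max(abs(numGrad(function(z) L(x, w, z), b) - g$db)), 1e-7)
})

test_that("max pooling follows the floor rule and routes gradients to argmaxes", {
  set.seed(2)
  x <- array(rnorm(7 * 5 * 2 * 2), c(7, 5, 2, 2))
  mp <- coroflow:::.cfMaxPool2Forward(x)
  expect_equal(dim(mp$y), c(3L, 2L, 2L, 2L))  # floor(7/2), floor(5/2)
  expect_equal(mp$y[1, 1, 1, 1], max(x[1:2, 1:2, 1, 1]))
  dy <- array(rnorm(length(mp$y)), dim(mp$y))
  dx <- coroflow:::.cfMaxPool2Backward(mp$idx, dy, 7L, 5L)
  num <- numGrad(function(z) sum(coroflow:::.cfMaxPool2Forward(z)$y * dy), x)
  expect_lt(max(abs(num - dx)), 1e-7)
})

test_that("fused batch-norm + ReLU gradients are exact", {
  set.seed(3)
  x <- array(rnorm(5 * 4 * 3 * 2), c(5, 4, 3, 2))
  g <- runif(3, 0.5, 1.5); be <- rnorm(3)
  dy <- array(rnorm(length(x)), dim(x))
  fw <- coroflow:::.cfBNReluForward(x, g, be, 1e-5)
  expect_equal(fw$y, pmax(coroflow:::.cfBatchNormForward(x, g, be, 1e-5)$y, 0))
  bw <- coroflow:::.cfBNReluBackward(x, dy, fw$mean, fw$var, g, be, 1e-5)
  L <- function(x_, g_, b_) sum(coroflow:::.cfBNReluForward(x_, g_, b_, 1e-5)$y * dy)
  expect_lt(max(abs(numGrad(function(z) L(z, g, be), x) - bw$dx)), 1e-6)
  expect_lt(max(abs(numGrad(function(z) L(x, z, be), g) - bw$dgamma)), 1e-6)
  expect_lt(max(abs(numGrad(function(z) L(x, g, z), be) - bw$dbeta)), 1e-6)
})

test_that("1D dilated convolution matches a direct reference and its gradients", {
  set.seed(4)
  S <- 9; Cin <- 3; Cout <- 2
  x <- matrix(rnorm(S * Cin), S, Cin)
  w <- array(rnorm(3 * Cin * Cout), c(3, Cin, Cout))
  b <- rnorm(Cout)
  for (dil in c(1L, 2L)) {
    y <- coroflow:::.conv1dF(x, w, b, dil)
    ref <- matrix(0, S, Cout)
    for (i in 1:S) for (co in 1:Cout) {
      s <- b[co]
      for (j in 1:3) {
        ii <- i + (j - 2) * dil
        if (ii >= 1 && ii <= S)
          s <- s + sum(x[ii, ] * w[j, , co])
      }
      ref[i, co] <- s
    }
    expect_lt(max(abs(y - ref)), 1e-12)
    dy <- matrix(rnorm(S * Cout), S, Cout)
    g <- coroflow:::.conv1dB(x, w, dil, dy)
    L <- function(x_, w_, b_) sum(coroflow:::.conv1dF(x_, w_, b_, dil) * dy)
    expect_lt(max(abs(numGrad(function(z) L(z, w, b), x) - g$dx)), 1e-7)
    expect_lt(max(abs(numGrad(function(z) L(x, z, b), w) - g$dw)), 1e-7)
    expect_lt(max(abs(numGrad(function(z) L(x, w, z), b) - g$db)), 1e-7)
  }
})

test_that("instance norm, layer norm and attention backward passes are exact", {
  set.seed(5)
  P <- 6; C <- 4
  x <- matrix(rnorm(P * C), P, C)
  g <- runif(C, 0.5, 1.5); be <- rnorm(C)
  dy <- matrix(rnorm(P * C), P, C)

  fw <- coroflow:::.instNormF(x, g, be)
  bw <- coroflow:::.instNormB(fw, g, dy)
  expect_lt(max(abs(numGrad(function(z)
    sum(coroflow:::.instNormF(z, g, be)$y * dy), x) - bw$dx)), 1e-6)
  expect_lt(max(abs(numGrad(function(z)
    sum(coroflow:::.instNormF(x, z, be)$y * dy), g) - bw$dg)), 1e-6)

  lf <- coroflow:::.layerNormF(x, g, be)
  lb <- coroflow:::.layerNormB(lf, g, dy)
  expect_lt(max(abs(numGrad(function(z)
    sum(coroflow:::.layerNormF(z, g, be)$y * dy), x) - lb$dx)), 1e-6)

  p <- list(Wq = matrix(rnorm(16), 4), bq = rnorm(4),
            Wk = matrix(rnorm(16), 4), bk = rnorm(4),
            Wv = matrix(rnorm(16), 4), bv = rnorm(4),
            Wo = matrix(rnorm(16), 4), bo = rnorm(4))
  mf <- coroflow:::.mhaF(x, p, heads = 2L)
  mb <- coroflow:::.mhaB(x, p, mf, dy, heads = 2L)
  expect_lt(max(abs(numGrad(function(z)
    sum(coroflow:::.mhaF(z, p, 2L)$y * dy), x) - mb$dx)), 1e-6)
  for (nm in names(p)) {
    num <- numGrad(function(z) {
      p2 <- p; p2[[nm]] <- z
      sum(coroflow:::.mhaF(x, p2, 2L)$y * dy)
    }, p[[nm]])
    expect_lt(max(abs(num - mb$grads[[nm]])), 1e-6)
  }
})

test_that("adaptive sum pooling spreads the remainder over proximal bins", {
  expect_equal(coroflow:::.binSizes(12L, 5L), c(3L, 3L, 2L, 2L, 2L))
  expect_equal(coroflow:::.binSizes(1L, 5L), c(1L, 0L, 0L, 0L, 0L))
  x <- matrix(1:24, 12, 2)
  y <- coroflow:::.sumPoolBinsF(x, 5L)
  expect_equal(y[1, 1], sum(x[1:3, 1]))
  expect_equal(y[5, 2], sum(x[11:12, 2]))
  expect_equal(colSums(y), colSums(x))
})

test_that("cyclic learning rate hits its endpoints", {
  expect_equal(cyclicLearningRate(0, 5e-4, 1e-5, 40), 5e-4)
  expect_equal(cyclicLearningRate(20, 5e-4, 1e-5, 40), 1e-5)
  expect_equal(cyclicLearningRate(40, 5e-4, 1e-5, 40), 5e-4)
  lrs <- vapply(0:80, cyclicLearningRate, numeric(1))
  expect_true(all(lrs >= 1e-5 & lrs <= 5e-4))
})
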