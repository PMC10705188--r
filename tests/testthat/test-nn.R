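# Gradient correctness of the volumetric network engine, checked against
# central finite differences on tiny layers. The engine underpins the GAN,
# the classifier, the feature extractor and the style-refinement blending,
# so these checks anchor everything downstream.

nnEnv <- asNamespace("ctGAN3D")

test_that("conv3d forward/backward match finite differences", {
  withr::local_seed(1)
  layer <- nnEnv$makeConv3d(c(4L, 4L, 4L), 2L, 3L, k = 3L, stride = 1L,
                            activation = "tanh")
  x <- array(rnorm(64 * 2 * 2), c(64, 2, 2))
  wOut <- array(rnorm(64 * 3 * 2), c(64, 3, 2))
  lossOf <- function(lay, xx) {
    fw <- nnEnv$layerForward(lay, xx, training = TRUE)
    sum(fw$y * wOut)
  }
  fw <- nnEnv$layerForward(layer, x, training = TRUE)
  bw <- nnEnv$layerBackward(layer, fw$cache, wOut)
  # input gradient
  idx <- sample(length(x), 8)
  num <- numericGrad(function(xx) lossOf(layer, array(xx, dim(x))),
                     as.vector(x), idx)
  expect_equal(as.vector(bw$dx)[idx], num, tolerance = 1e-5)
  # weight gradient
  idxW <- sample(length(layer$params$W), 8)
  numW <- numericGrad(function(w) {
    l2 <- layer; l2$params$W <- matrix(w, nrow(layer$params$W)); lossOf(l2, x)
  }, as.vector(layer$params$W), idxW)
  expect_equal(as.vector(bw$grads$W)[idxW], numW, tolerance = 1e-5)
})

test_that("transposed conv forward doubles the grid and matches finite differences", {
  withr::local_seed(2)
  layer <- nnEnv$makeConvT3d(c(4L, 4L, 4L), 3L, 2L, activation = "relu")
  x <- array(rnorm(64 * 3), c(64, 3, 1))
  fw <- nnEnv$layerForward(layer, x, training = TRUE)
  expect_identical(dim(fw$y), c(512L, 2L, 1L))     # 8^3 output grid
  wOut <- array(rnorm(512 * 2), c(512, 2, 1))
  bw <- nnEnv$layerBackward(layer, fw$cache, wOut)
  lossOf <- function(xx) {
    f <- nnEnv$layerForward(layer, array(xx, dim(x)), training = TRUE)
    sum(f$y * wOut)
  }
  idx <- sample(length(x), 8)
  num <- numericGrad(lossOf, as.vector(x), idx)
  expect_equal(as.vector(bw$dx)[idx], num, tolerance = 1e-5)
})

test_that("batchnorm training-mode backward matches finite differences", {
  withr::local_seed(3)
  layer <- nnEnv$makeBatchNorm(2L)
  layer$params$gamma <- c(1.5, 0.7)
  layer$params$beta <- c(0.1, -0.2)
  x <- array(rnorm(10 * 2 * 3), c(10, 2, 3))
  wOut <- array(rnorm(10 * 2 * 3), c(10, 2, 3))
  fw <- nnEnv$layerForward(layer, x, training = TRUE)
  bw <- nnEnv$layerBackward(layer, fw$cache, wOut)
  lossOf <- function(xx) {
    f <- nnEnv$layerForward(layer, array(xx, dim(x)), training = TRUE)
    sum(f$y * wOut)
  }
  idx <- sample(length(x), 10)
  num <- numericGrad(lossOf, as.vector(x), idx)
  expect_equal(as.vector(bw$dx)[idx], num, tolerance = 1e-4)
})

test_that("max pooling halves the grid and routes gradients to the argmax", {
  withr::local_seed(4)
  layer <- nnEnv$makePool3d(c(4L, 4L, 4L), 2L)
  x <- array(rnorm(64 * 2), c(64, 2, 1))
  fw <- nnEnv$layerForward(layer, x)
  expect_identical(dim(fw$y), c(8L, 2L, 1L))
  for (c in 1:2) expect_equal(max(fw$y[, c, 1]), max(x[, c, 1]))
  dy <- array(1, c(8, 2, 1))
  bw <- nnEnv$layerBackward(layer, fw$cache, dy)
  # each pooling block contributes exactly one unit of gradient
  expect_equal(sum(bw$dx), 16)
  expect_identical(sum(bw$dx != 0), 16L)
})

test_that("a conv-pool-dense chain backpropagates end to end", {
  withr::local_seed(5)
  layers <- list(
    conv = nnEnv$makeConv3d(c(4L, 4L, 4L), 1L, 2L, activation = "relu"),
    pool = nnEnv$makePool3d(c(4L, 4L, 4L), 2L),
    flat = nnEnv$makeFlatten(8L, 2L),
    out = nnEnv$makeDense(16L, 1L, activation = "sigmoid"))
  net <- list(kind = "seq", layers = layers)
  x <- array(rnorm(64 * 2), c(64, 1, 2))
  fw <- nnEnv$seqForward(net, x, training = TRUE)
  expect_identical(dim(fw$out), c(2L, 1L))
  expect_true(all(fw$out > 0 & fw$out < 1))
  bw <- nnEnv$seqBackward(net, fw$caches, matrix(1, 2, 1))
  lossOf <- function(xx) {
    f <- nnEnv$seqForward(net, array(xx, dim(x)), training = TRUE)
    sum(f$out)
  }
  idx <- sample(length(x), 6)
  num <- numericGrad(lossOf, as.vector(x), idx)
  expect_equal(as.vector(bw$dx)[idx], num, tolerance = 1e-5)
})
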