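test_that("Frechet distance: identity, closed form, symmetry and sqrtm oracle", {
  withr::local_seed(1)
  f <- matrix(rnorm(200), 20, 10)
  a <- featureStats(f)
  expect_lt(abs(frechetDistance(a, a)), 1e-6)
  # closed form: C1 = C2 -> d^2 = ||mu1 - mu2||^2
  b <- new("FeatureStats", mu = a@mu + c(1, rep(0, 9)), sigma = a@sigma,
           n = a@n)
  expect_equal(frechetDistance(a, b), 1, tolerance = 1e-9)
  # mu shift + identity covariances
  i1 <- new("FeatureStats", mu = rep(0, 5), sigma = diag(5), n = 10L)
  i2 <- new("FeatureStats", mu = c(1, 0, 0, 0, 0), sigma = diag(5), n = 10L)
  expect_equal(frechetDistance(i1, i2), 1, tolerance = 1e-12)
  # agreement with an eigendecomposition sqrtm oracle on random SPD pairs
  for (d in c(3L, 5L, 16L)) {
    A <- crossprod(matrix(rnorm(d * d), d))
    B <- crossprod(matrix(rnorm(d * d), d))
    sa <- new("FeatureStats", mu = rnorm(d), sigma = A, n = 10L)
    sb <- new("FeatureStats", mu = rnorm(d), sigma = B, n = 10L)
    e <- eigen(A %*% B)
    S <- Re(e$vectors %*% diag(sqrt(as.complex(e$values)), d) %*%
              solve(e$vectors))
    oracle <- sum((sa@mu - sb@mu)^2) + sum(diag(A + B - 2 * S))
    expect_equal(frechetDistance(sa, sb), oracle, tolerance = 1e-8)
    expect_equal(frechetDistance(sa, sb), frechetDistance(sb, sa),
                 tolerance = 1e-8)
    expect_gte(frechetDistance(sa, sb), 0)
  }
  # the printed (no square root) form does not vanish at identity
  expect_gt(abs(frechetDistance(a, a, printedForm = TRUE)), 1e-6)
  expect_error(frechetDistance(i1, a), "dimensions differ")
})

test_that("the cold-started extractor is seeded and side-agnostic", {
  e1 <- buildFeatureExtractor(seed = 42L)
  e2 <- buildFeatureExtractor(seed = 42L)
  expect_identical(e1$weights, e2$weights)
  v32 <- withr::with_seed(1, tanh(array(rnorm(32^3), c(32, 32, 32))))
  f1 <- extractFeatures(e1, list(v32))
  f2 <- extractFeatures(e2, list(v32))
  expect_identical(f1, f2)
  expect_identical(ncol(f1), 512L)
  v64 <- withr::with_seed(2, tanh(array(rnorm(64^3), c(64, 64, 64))))
  expect_identical(ncol(extractFeatures(e1, list(v64))), 512L)
  # zero input still yields finite features
  expect_true(all(is.finite(extractFeatures(e1, list(array(0, c(16, 16, 16)))))))
  expect_error(extractFeatures(e1, list(array(0, c(8, 8, 8)))), ">= 16")
  # a different seed changes the weights
  expect_false(identical(buildFeatureExtractor(seed = 1L)$weights,
                         e1$weights))
})

test_that("f3d separates noise from held-out phantoms and is order-invariant", {
  ex <- buildFeatureExtractor()
  real <- phantomPatchSet(6L, seedBase = 300L)
  held <- phantomPatchSet(6L, seedBase = 400L)
  noise <- noisePatchSet(6L)
  expect_lt(abs(f3d(real, real, ex)), 1e-6)
  dHeld <- f3d(real, held, ex)
  dNoise <- f3d(real, noise, ex)
  expect_lt(dHeld, dNoise)
  # invariance to storage order
  shuf <- PatchSet(patches(held)[c(3, 1, 5, 2, 6, 4)], "tumor")
  expect_equal(f3d(real, shuf, ex), dHeld, tolerance = 1e-8)
  expect_error(f3d(PatchSet(patches(real)[1], "tumor"), held, ex),
               "at least 2")
})

test_that("slice FID vanishes on identical sets and sees mean shifts", {
  backend <- buildFeatureExtractor(dims = 2L)
  set <- phantomPatchSet(5L, seedBase = 500L)
  for (plane in c("sagittal", "axial", "coronal"))
    expect_lt(abs(sliceFid(set, set, plane, backend)), 1e-6)
  # closed-form Gaussian check: equal covariance, shifted features
  f <- withr::with_seed(3, matrix(rnorm(100), 20, 5))
  shift <- c(2, -1, 0, 1, 3)
  sa <- featureStats(f)
  sb <- featureStats(sweep(f, 2, -shift))
  expect_equal(frechetDistance(sa, sb), sum(shift^2), tolerance = 1e-8)
  expect_error(sliceFid(set, set, "oblique", backend), "arg")
})

test_that("slice PSNR follows the formula, the cap and seeded pairing", {
  a <- array(0, c(16, 16, 16))
  b <- a; b[] <- 0.2
  sa <- PatchSet(list(a, a), "tumor")
  sb <- PatchSet(list(b, b), "tumor")
  # uniform 0.2 difference: 10 log10(4 / 0.04) = 20 dB
  expect_equal(slicePsnr(sa, sb, "axial", "index"), 20, tolerance = 1e-9)
  expect_equal(slicePsnr(sa, sa, "axial", "index"), 99)
  set <- phantomPatchSet(6L, seedBase = 600L)
  other <- phantomPatchSet(6L, seedBase = 700L)
  p1 <- slicePsnr(set, other, "coronal", "random", seed = 4L)
  p2 <- slicePsnr(set, other, "coronal", "random", seed = 4L)
  expect_identical(p1, p2)
  expect_error(slicePsnr(sa, PatchSet(list(b), "tumor")), "equally sized")
})

test_that("MMD^2: singleton closed form, non-negativity, degenerate zero", {
  a <- matrix(c(0, 0), 1)
  b <- matrix(c(1, 1), 1)
  expect_equal(mmd2(a, b, bandwidth = 1, unbiased = FALSE),
               2 - 2 * exp(-2 / 2), tolerance = 1e-12)
  withr::local_seed(5)
  x <- matrix(rnorm(60), 20, 3)
  y <- matrix(rnorm(60, 2), 20, 3)
  expect_gte(mmd2(x, y, unbiased = FALSE), 0)
  expect_gt(mmd2(x, y), mmd2(x, matrix(rnorm(60), 20, 3)))
  same <- matrix(1, 4, 2)
  expect_identical(mmd2(same, same), 0)
  expect_error(mmd2(a, b), ">= 2")
})

test_that("MS-SSIM diversity: identical sets give 1, noise scores low", {
  v <- withr::with_seed(6, tanh(array(rnorm(32^3), c(32, 32, 32))))
  same <- PatchSet(list(v, v, v), "tumor")
  expect_equal(msSsimDiversity(same, nPairs = 3L), 1, tolerance = 1e-9)
  noise <- noisePatchSet(6L, side = 32L, seed = 7L)
  val <- msSsimDiversity(noise, nPairs = 10L, seed = 8L)
  expect_lt(val, 0.2)
  expect_gte(val, 0)
  expect_identical(val, msSsimDiversity(noise, nPairs = 10L, seed = 8L))
  tiny <- matrix(0, 8, 8)
  expect_error(msSsim2d(tiny, tiny), "minimum side")
  # volumetric single-scale variant: self-similarity is 1
  expect_equal(ssim3d(v, v), 1, tolerance = 1e-9)
})

test_that("metric reports bundle all quantities with valid ranges", {
  real <- phantomPatchSet(4L, seedBase = 800L)
  synth <- phantomPatchSet(4L, seedBase = 900L)
  rep <- metricReport(real, synth)
  expect_true(all(rep$sliceFid >= 0))
  expect_true(all(is.finite(rep$slicePsnr)))
  expect_gte(rep$f3d, 0)
  expect_true(rep$msSsim >= 0 && rep$msSsim <= 1)
  expect_identical(rep$extractorSeed, 42L)
})
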