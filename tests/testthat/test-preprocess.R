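test_that("window normalization maps endpoints, midpoint and clips", {
  cfg <- preprocessConfig()
  v <- CTVolume(array(c(-100, 170, 35, 1298, -408, 0, 100, -50),
                      c(2, 2, 2)), spacing = 1)
  nv <- normalizeWindow(v, cfg)
  x <- voxels(nv)
  expect_equal(x[1], -1)                 # window low
  expect_equal(x[2], 1)                  # window high
  expect_equal(x[3], 0)                  # midpoint
  expect_equal(x[4], 1)                  # clipped from 1298
  expect_equal(x[5], -1)                 # clipped from -408
  expect_identical(intensityDomain(nv), "normalized")
  expect_error(normalizeWindow(nv, cfg), "raw")

  # monotonicity over random HU draws
  hu <- withr::with_seed(1, sort(runif(50, -500, 1400)))
  mapped <- voxels(normalizeWindow(
    CTVolume(array(hu, c(50, 1, 1)), spacing = 1), cfg))
  expect_true(all(diff(as.vector(mapped)) >= 0))
})

test_that("metal suppression replaces exactly the above-threshold voxels", {
  cfg <- preprocessConfig()
  v <- array(60, c(6, 6, 6))
  v[2, 2, 2] <- 1200
  v[5, 5, 5] <- 200                       # boundary: strict inequality
  mask <- array(0, c(6, 6, 6)); mask[2:5, 2:5, 2:5] <- 1
  vol <- CTVolume(v, spacing = 1)
  pm <- MaskVolume(mask, "pancreas")
  out <- suppressMetal(vol, pm, cfg)
  expected <- mean(v[mask != 0])          # pre-replacement pancreas mean
  expect_equal(voxels(out)[2, 2, 2], expected)
  expect_equal(voxels(out)[5, 5, 5], 200) # untouched at the threshold
  changed <- voxels(out) != v
  expect_identical(which(changed), which(v > 200))

  # no-op when nothing exceeds the threshold
  v2 <- CTVolume(array(60, c(6, 6, 6)), spacing = 1)
  expect_identical(voxels(suppressMetal(v2, pm, cfg)), voxels(v2))
  expect_error(suppressMetal(vol, MaskVolume(array(0, c(6, 6, 6)),
                                             "pancreas"), cfg), "empty")
})

test_that("isotropic resampling matches an independent trilinear oracle", {
  # identity
  a <- withr::with_seed(2, array(rnorm(4^3), c(4, 4, 4)))
  expect_identical(voxels(resampleIsotropic(CTVolume(a, spacing = 1), 1)), a)
  # constant volume stays constant under anisotropic resampling
  cc <- resampleIsotropic(CTVolume(array(5, c(4, 4, 4)),
                                   spacing = c(2, 1, 3)), 1)
  expect_true(all(voxels(cc) == 5))
  expect_identical(dim(voxels(cc)), c(8L, 4L, 12L))

  # ramp at 2 mm -> 1 mm vs a triple-loop voxel-center trilinear oracle
  ramp <- array(0, c(4, 4, 4))
  for (k in 1:4) ramp[, , k] <- (k - 1) * 10
  out <- voxels(resampleIsotropic(CTVolume(ramp, spacing = 2), 1))
  oracle <- array(0, c(8, 8, 8))
  src <- function(i) min(max((i - 0.5) / 2 + 0.5, 1), 4)
  for (i in 1:8) for (j in 1:8) for (k in 1:8) {
    ci <- src(i); cj <- src(j); ck <- src(k)
    acc <- 0
    for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
      gi <- min(floor(ci) + di, 4); gj <- min(floor(cj) + dj, 4)
      gk <- min(floor(ck) + dk, 4)
      wi <- if (di == 0) 1 - (ci - floor(ci)) else ci - floor(ci)
      wj <- if (dj == 0) 1 - (cj - floor(cj)) else cj - floor(cj)
      wk <- if (dk == 0) 1 - (ck - floor(ck)) else ck - floor(ck)
      acc <- acc + wi * wj * wk * ramp[gi, gj, gk]
    }
    oracle[i, j, k] <- acc
  }
  expect_lt(max(abs(out - oracle)), 1e-5)
  expect_error(resampleIsotropic(CTVolume(array(0, c(1, 4, 4)), spacing = 1),
                                 1), "degenerate")
})

test_that("patch cropping centers on the centroid and pads with -1", {
  v <- CTVolume(withr::with_seed(3, array(runif(40^3, -1, 1), c(40, 40, 40))),
                spacing = 1, intensityDomain = "normalized")
  m <- array(0, c(40, 40, 40)); m[19:22, 19:22, 19:22] <- 1
  p <- cropPatch(v, MaskVolume(m, "tumor"), 16L)
  expect_identical(dim(p), c(16L, 16L, 16L))
  # centroid at 20.5 -> rounds to 20; half-open [12, 28)
  expect_identical(p[1, 1, 1], voxels(v)[12, 12, 12])
  expect_identical(attr(p, "tissueClass"), "tumor")

  # centroid near a face: output equals an independent pad-then-slice oracle
  m2 <- array(0, c(40, 40, 40)); m2[1:3, 19:22, 19:22] <- 1
  p2 <- cropPatch(v, MaskVolume(m2, "tumor"), 16L)
  padded <- array(-1, c(40 + 16, 40, 40))
  padded[17:56, , ] <- voxels(v)
  ctr <- round(colMeans(which(m2 != 0, arr.ind = TRUE)))   # (2, 20, 20)
  lo <- ctr - 8L + c(16L, 0L, 0L)
  oracle <- padded[lo[1]:(lo[1] + 15L), lo[2]:(lo[2] + 15L),
                   lo[3]:(lo[3] + 15L)]
  expect_identical(as.vector(p2), as.vector(oracle))
  expect_error(cropPatch(v, MaskVolume(array(0, c(40, 40, 40)), "tumor"),
                         16L), "empty")
})

test_that("rotation augmentation yields 15 shape-preserving copies", {
  p <- phantomPatch(4L)
  aug <- augmentRotations(p)
  expect_identical(length(aug), 15L)
  expect_true(all(vapply(patches(aug), function(x)
    identical(dim(x), c(16L, 16L, 16L)), TRUE)))
  # zero rotation is the identity
  same <- augmentRotations(p, angles = 0, axes = 1L)
  expect_identical(patches(same)[[1]], array(p, dim(p)))
  # rotated copies differ from the original
  expect_false(identical(patches(aug)[[1]], array(p, dim(p))))
})

test_that("the preprocessing chain is deterministic end to end", {
  scan <- makePhantomScan(smallPhantomConfig(8L, side = 32L))
  cfg <- preprocessConfig(tumorSide = 8L, pancreasSide = 16L)
  r1 <- preprocessScan(scan$volume, scan$tumorMask, scan$pancreasMask, cfg)
  r2 <- preprocessScan(scan$volume, scan$tumorMask, scan$pancreasMask, cfg)
  expect_identical(r1, r2)
  expect_identical(dim(r1$tumor), c(8L, 8L, 8L))
  expect_identical(dim(r1$pancreas), c(16L, 16L, 16L))
  expect_true(all(abs(r1$pancreas) <= 1))
})
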