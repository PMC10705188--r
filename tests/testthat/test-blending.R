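test_that("tumor mask extraction thresholds strictly and keeps the largest component", {
  # two disjoint blobs: 4x4x4 = 64 voxels vs 2x2x2 = 8 voxels
  t <- array(-1, c(12, 12, 12))
  t[2:5, 2:5, 2:5] <- 0.8
  t[9:10, 9:10, 9:10] <- 0.8
  m <- extractTumorMask(t, maskThreshold = 0)
  expect_identical(sum(voxels(m)), 64)
  expect_identical(sum(voxels(m)[2:5, 2:5, 2:5]), 64)
  # saturation: everything above threshold -> full cube before erosion
  full <- extractTumorMask(array(0.5, c(6, 6, 6)), maskThreshold = 0)
  expect_identical(sum(voxels(full)), 216)
  # threshold above the maximum errors
  expect_error(extractTumorMask(t, maskThreshold = 0.9), "empty")
  # strictness at the boundary: a voxel exactly at the threshold is excluded
  eq <- array(0, c(6, 6, 6)); eq[3, 3, 3] <- 0.6; eq[5, 5, 5] <- 0.5
  expect_identical(sum(voxels(extractTumorMask(eq, maskThreshold = 0.5))), 1)
  # erosion shrinks the component
  er <- extractTumorMask(t, maskThreshold = 0, erode = TRUE)
  expect_lt(sum(voxels(er)), 64)
  # Otsu default records the threshold it picked
  tum <- phantomPatch(31L)
  auto <- extractTumorMask(tum)
  expect_true(attr(auto, "threshold") > -1 && attr(auto, "threshold") < 1)
})

test_that("copy-paste blending is a voxel-exact splice", {
  tumor <- phantomPatch(32L)
  pan <- texturePatch(33L, side = 32L)
  req <- blendRequest(tumor, pan, method = "I")
  out <- voxels(blendCopyPaste(req))
  m <- voxels(extractTumorMask(tumor)) != 0
  # independent index-wise splice oracle
  oracle <- pan
  off <- req$offset
  for (i in 1:16) for (j in 1:16) for (k in 1:16)
    if (m[i, j, k])
      oracle[off[1] + i - 1, off[2] + j - 1, off[3] + k - 1] <- tumor[i, j, k]
  expect_identical(out, oracle)
  # outside the mask: bit-identical to the pancreas input
  big <- array(FALSE, dim(pan))
  big[off[1]:(off[1] + 15), off[2]:(off[2] + 15), off[3]:(off[3] + 15)] <- m
  expect_identical(out[!big], pan[!big])
  # explicit checkerboard mask at offset (9,9,9) via a crafted tumor
  cb <- array(rep(c(0.8, -1), length.out = 8^3), c(8, 8, 8))
  req2 <- blendRequest(cb, pan, offset = c(9, 9, 9), method = "I",
                       maskThreshold = 0)
  out2 <- voxels(blendCopyPaste(req2))
  m2 <- voxels(extractTumorMask(cb, 0)) != 0
  for (v in which(m2)) {
    ijk <- arrayInd(v, dim(cb))
    expect_identical(out2[ijk[1] + 8, ijk[2] + 8, ijk[3] + 8], cb[v])
  }
  # an all-below-threshold tumor errors rather than silently no-oping
  expect_error(blendCopyPaste(blendRequest(array(-1, c(8, 8, 8)), pan,
                                           method = "I",
                                           maskThreshold = 0)), "empty")
  # idempotence: re-blending the same tumor changes nothing
  req3 <- blendRequest(tumor, out, method = "I",
                       maskThreshold = attr(extractTumorMask(tumor),
                                            "threshold"))
  expect_identical(voxels(blendCopyPaste(req3)), out)
})

test_that("tumor placement outside the pancreas cube is rejected", {
  tumor <- phantomPatch(34L)
  pan <- texturePatch(35L, side = 32L)
  expect_error(blendRequest(tumor, pan, offset = c(20, 1, 1)), "fit")
  expect_error(blendRequest(tumor, pan, maskThreshold = 1.5), "maskThreshold")
})

test_that("seamless blending honors Dirichlet boundaries and descends", {
  tumor <- phantomPatch(36L)
  pan <- texturePatch(37L, side = 32L)
  req <- blendRequest(tumor, pan, method = "II", iterations = 40L)
  out <- blendSeamless(req)
  losses <- attr(out, "losses")
  expect_true(all(is.finite(losses)))
  expect_lte(tail(losses, 1), losses[1])
  # constant tumor into constant pancreas of the same value: zero loss
  cT <- array(0.5, c(8, 8, 8))
  cP <- array(0.5, c(24, 24, 24))
  cOut <- blendSeamless(blendRequest(cT, cP, method = "II",
                                     iterations = 5L, maskThreshold = 0))
  expect_equal(attr(cOut, "losses")[1], 0)
  expect_identical(voxels(cOut), cP)
  # voxels on and outside the mask rim equal the pancreas input
  m <- voxels(extractTumorMask(tumor)) != 0
  inner <- ctGAN3D:::erode6(m)
  rim <- m & !inner
  off <- req$offset
  big <- array(FALSE, dim(pan))
  big[off[1]:(off[1] + 15), off[2]:(off[2] + 15), off[3]:(off[3] + 15)] <- inner
  expect_identical(voxels(out)[!big], pan[!big])
})

test_that("style refinement descends and reduces to stage 1 in the content limit", {
  tumor <- phantomPatch(38L)
  pan <- texturePatch(39L, side = 32L)
  reqIII <- blendRequest(tumor, pan, method = "III", iterations = 6L)
  out <- blendStylized(reqIII)
  losses <- attr(out, "losses")
  expect_true(all(is.finite(losses)))
  expect_lte(tail(losses, 1), losses[1])
  expect_true(all(abs(voxels(out)) <= 1))
  # locality
  m <- voxels(extractTumorMask(tumor)) != 0
  off <- reqIII$offset
  big <- array(FALSE, dim(pan))
  big[off[1]:(off[1] + 15), off[2]:(off[2] + 15), off[3]:(off[3] + 15)] <- m
  expect_identical(voxels(out)[!big], pan[!big])
  # content-only weighting: stage 2 stays at the stage-1 optimum
  reqC <- blendRequest(tumor, pan, method = "III", iterations = 4L,
                       weights = list(gradient = 0, style = 0,
                                      content = 1, tv = 0))
  outC <- blendStylized(reqC)
  stage1 <- blendSeamless(blendRequest(tumor, pan, method = "II",
                                       iterations = reqC$iterations,
                                       maskThreshold = reqC$maskThreshold))
  expect_equal(voxels(outC), voxels(stage1), tolerance = 1e-8)
})

test_that("all blending methods preserve shape and the normalized range", {
  tumor <- phantomPatch(40L)
  pan <- texturePatch(41L, side = 32L)
  for (method in c("I", "II", "III")) {
    req <- blendRequest(tumor, pan, method = method, iterations = 4L)
    out <- blendVolumes(req)
    expect_identical(dim(voxels(out)), dim(pan))
    expect_true(all(abs(voxels(out)) <= 1))
    expect_identical(intensityDomain(out), "normalized")
  }
})
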