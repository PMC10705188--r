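test_that("generator geometry: halving encoder, shape-preserving U-Net, tanh bounds", {
  cfg <- ganConfig(side = 32L, unetDepth = 4L, baseChannels = 2L,
                   epochs = 20L, seed = 1L)
  gen <- withr::with_seed(1, buildGenerator(cfg))
  # encoder spatial sizes 32 -> 16 -> 8 -> 4 -> 2
  sizes <- vapply(1:4, function(l)
    gen$layers[[paste0("enc", l)]]$geom$outDim[1], 0L)
  expect_identical(sizes, c(16L, 8L, 4L, 2L))
  z <- withr::with_seed(2, array(rnorm(32^3), c(32^3, 1, 1)))
  fw <- ctGAN3D:::ganGeneratorForward(gen, z)
  expect_identical(dim(fw$out), c(32768L, 1L, 1L)) # output shape = input shape
  expect_true(all(fw$out > -1 & fw$out < 1))       # strict tanh bounds
  expect_error(ganConfig(side = 24L, unetDepth = 4L), "divisible")
})

test_that("generator contract holds across random valid configs", {
  withr::local_seed(7)
  for (i in 1:3) {
    depth <- sample(1:2, 1)
    side <- sample(c(8L, 16L), 1)
    cfg <- ganConfig(side = side, unetDepth = depth,
                     baseChannels = sample(2:4, 1), epochs = 20L, seed = i)
    gen <- buildGenerator(cfg)
    z <- array(rnorm(side^3 * 2), c(side^3, 1, 2))
    out <- ctGAN3D:::ganGeneratorForward(gen, z)$out
    expect_equal(dim(out), c(side^3, 1, 2))
    expect_true(all(abs(out) < 1))
  }
})

test_that("discriminator halves through pooling and emits batched sigmoids", {
  cfg <- ganConfig(side = 16L, unetDepth = 2L, baseChannels = 4L,
                   epochs = 20L, seed = 1L)
  dis <- withr::with_seed(3, buildDiscriminator(cfg))
  pools <- grep("^pool", names(dis$layers))
  sizes <- vapply(dis$layers[pools], function(l) l$geom$outDim[1], 0L)
  expect_identical(unname(sizes), c(8L, 4L, 2L))
  x <- withr::with_seed(4, array(runif(16^3 * 3, -1, 1), c(16^3, 1, 3)))
  out <- ctGAN3D:::seqForward(dis, x)$out
  expect_identical(dim(out), c(3L, 1L))
  expect_true(all(out > 0 & out < 1))
})

test_that("adversarial losses match their closed forms", {
  l <- adversarialLosses(rep(0.5, 4), rep(0.5, 4))
  expect_equal(l$discriminatorObjective, 2 * log(0.5), tolerance = 1e-12)
  expect_equal(l$generatorLoss, log(0.5), tolerance = 1e-12)
  # optimum of the discriminator objective
  lOpt <- adversarialLosses(rep(1 - 1e-9, 4), rep(1e-9, 4))
  expect_gt(lOpt$discriminatorObjective, -1e-5)
  expect_lte(lOpt$discriminatorObjective, 0)
  # the objective decreases as fakes fool the discriminator (finite diff)
  obj <- function(pf) adversarialLosses(rep(0.9, 4),
                                        rep(pf, 4))$discriminatorObjective
  expect_lt(obj(0.6), obj(0.4))
  expect_error(adversarialLosses(numeric(0), 0.5), "empty")
})

test_that("short training runs are reproducible with checkpoints on schedule", {
  train <- phantomPatchSet(8L)
  cfg <- tinyGanConfig(epochs = 8L, seed = 11L)
  cfg$checkpointInterval <- 4L  # checkpoints at 4 and 8
  log1 <- trainGan(train, cfg)
  log2 <- trainGan(train, cfg)
  expect_identical(log1@gLoss, log2@gLoss)
  expect_identical(log1@dLoss, log2@dLoss)
  expect_identical(names(log1@checkpoints), c("4", "8"))
  expect_true(all(is.finite(log1@gLoss)))
  expect_error(trainGan(train, tinyGanConfig(epochs = 8L, batchSize = 32L)),
               "batchSize")
})

test_that("checkpoint selection returns the last epoch before a loss spike", {
  mkLog <- function(gl, interval = 20L) {
    ep <- seq_along(gl)
    cps <- ep[ep %% interval == 0]
    new("TrainLog", epochs = ep, gLoss = gl, dLoss = gl * 0,
        checkpoints = setNames(
          lapply(cps, function(e) list(epoch = e)), cps),
        config = list(), seed = 1L)
  }
  # flat curve: final checkpoint
  expect_identical(selectCheckpoint(mkLog(rep(0.7, 200))), 200L)
  # flat then a jump at epoch 120: last good checkpoint is 100
  spiky <- c(rep(0.7, 119), rep(5, 81))
  expect_identical(selectCheckpoint(mkLog(spiky)), 100L)
  # slowly decreasing: final checkpoint
  expect_identical(selectCheckpoint(mkLog(seq(0.75, 0.6, length.out = 200))),
                   200L)
  # negative-valued (saturating) losses: the magnitude-symmetric rule
  # still detects the collapse and backs off from the spiked tail
  negSpiky <- c(rep(-0.7, 119), rep(-0.7 / 5, 81))
  expect_lte(selectCheckpoint(mkLog(negSpiky)), 120L)
})

test_that("synthesis is deterministic, bounded and counts correctly", {
  train <- phantomPatchSet(8L)
  cfg <- tinyGanConfig(epochs = 4L, seed = 13L)
  cfg$checkpointInterval <- 4L
  log <- trainGan(train, cfg)
  ck <- log@checkpoints[["4"]]
  s1 <- synthesize(ck, 5L, seed = 2L)
  s2 <- synthesize(ck, 5L, seed = 2L)
  expect_identical(length(s1), 5L)
  expect_identical(patches(s1), patches(s2))
  expect_true(all(abs(unlist(patches(s1))) < 1))
  expect_identical(provenance(s1), "synthetic")
  expect_identical(length(synthesize(ck, 0L)), 0L)
  expect_error(synthesize(file.path(tempdir(), "no-such.rds"), 1L),
               "missing")
  # disk round trip
  p <- withr::local_tempfile(fileext = ".rds")
  saveCheckpoint(ck, p)
  expect_identical(patches(synthesize(p, 2L, seed = 9L)),
                   patches(synthesize(ck, 2L, seed = 9L)))
})
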