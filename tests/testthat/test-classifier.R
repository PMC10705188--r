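test_that("hold-out splitting is stratified, seeded and conserving", {
  vols <- lapply(1:428, function(i) array(0, c(16, 16, 16)))
  ds <- ClassifierDataset(vols, c(rep("tumor", 174), rep("healthy", 254)))
  sp <- splitHoldout(ds, 0.2, seed = 1L)
  tab <- table(datasetLabels(sp$test))
  expect_identical(as.integer(tab[["tumor"]]), 35L)
  expect_identical(as.integer(tab[["healthy"]]), 51L)
  tabTr <- table(datasetLabels(sp$train))
  expect_identical(as.integer(tabTr[["tumor"]]), 139L)
  expect_identical(as.integer(tabTr[["healthy"]]), 203L)
  expect_identical(length(sp$train) + length(sp$test), 428L)
  # seeded determinism
  sp2 <- splitHoldout(ds, 0.2, seed = 1L)
  expect_identical(datasetLabels(sp2$test), datasetLabels(sp$test))
  # rounding to an empty class errors
  small <- ClassifierDataset(vols[1:6], c(rep("tumor", 2), rep("healthy", 4)))
  expect_error(splitHoldout(small, 0.1, seed = 1L), "empty test")
  # single-class dataset errors
  onecl <- ClassifierDataset(vols[1:4], rep("tumor", 4))
  expect_error(splitHoldout(onecl, 0.2, seed = 1L), "absent")
})

test_that("synthetic items never leak into the test partition", {
  vols <- lapply(1:40, function(i) array(0, c(16, 16, 16)))
  ds <- ClassifierDataset(vols,
                          rep(c("tumor", "healthy"), each = 20),
                          provenance = rep(c("real-phantom", "synthetic"),
                                           20))
  sp <- splitHoldout(ds, 0.2, seed = 2L)
  expect_true(all(provenance(sp$test) != "synthetic"))
  expect_identical(length(sp$train) + length(sp$test), 40L)
  # adding synthetic items does not change the test partition
  real <- ClassifierDataset(vols[provenance(ds) != "synthetic"],
                            as.character(datasetLabels(ds))[
                              provenance(ds) != "synthetic"])
  spReal <- splitHoldout(real, 0.2, seed = 2L)
  expect_identical(length(spReal$test), length(sp$test))
})

test_that("training-set assembly follows the two configurations", {
  vols <- lapply(1:342, function(i) array(0, c(16, 16, 16)))
  trainReal <- ClassifierDataset(vols,
                                 c(rep("tumor", 139), rep("healthy", 203)))
  st <- lapply(1:114, function(i) array(0, c(16, 16, 16)))
  sh <- lapply(1:50, function(i) array(0, c(16, 16, 16)))
  cI <- assembleConfig(trainReal, st, sh, "I")
  expect_identical(length(cI), 342L)
  cII <- assembleConfig(trainReal, st, sh, "II")
  tab <- table(datasetLabels(cII))
  expect_identical(as.integer(tab[["tumor"]]), 253L)
  expect_identical(as.integer(tab[["healthy"]]), 253L)
  expect_identical(sum(provenance(cII) == "synthetic"), 164L)
  # mode II with zero synthetic items equals mode I
  c0 <- assembleConfig(trainReal, st, sh, "II", 0L, 0L)
  expect_identical(datasetLabels(c0), datasetLabels(cI))
  expect_error(assembleConfig(trainReal, st, sh, "II", 200L, 0L), "supply")
})

test_that("random rotations are seeded and uniform over the angle set", {
  v <- phantomPatch(51L)
  r1 <- augmentRandomRotation(v, seed = 5L)
  r2 <- augmentRandomRotation(v, seed = 5L)
  expect_identical(r1, r2)
  expect_identical(dim(r1), dim(v))
  expect_false(identical(r1, v))
  # angle frequencies over seeded draws: 0.25 +/- 0.02 each
  draws <- vapply(1:10000, function(i)
    ctGAN3D:::withSeed(i, {
      sample.int(3L, 1L)
      sample(c(5, 10, 20, 40), 1L)
    }), 0)
  freq <- table(draws) / 10000
  expect_true(all(abs(freq - 0.25) < 0.02))
})

test_that("classifier architecture follows the block/pool contract", {
  cfg <- tinyClassifierConfig()
  model <- withr::with_seed(1, buildClassifier(cfg))
  pools <- grep("^pool", names(model$layers))
  sizes <- vapply(model$layers[pools], function(l) l$geom$outDim[1], 0L)
  expect_identical(unname(sizes), c(8L, 4L, 2L, 1L))
  convCh <- vapply(grep("^conv", names(model$layers)), function(i)
    model$layers[[i]]$outCh, 0L)
  expect_identical(convCh, c(4L, 8L, 12L, 16L))
  expect_gt(model$paramCount, 0)
  # batched probability outputs
  x <- ctGAN3D:::stackCubes(lapply(1:3, function(i) phantomPatch(60L + i)))
  out <- ctGAN3D:::seqForward(model, x)$out
  expect_identical(dim(out), c(3L, 2L))
  expect_true(all(out > 0 & out < 1))
  expect_error(classifierConfig(side = 24L), "divisible")
  # paper-scale channel progression is the default
  expect_identical(classifierConfig()$channels, c(64L, 128L, 256L, 512L))
})

test_that("cross-validation folds partition the data with stratification", {
  labs <- rep(c("tumor", "healthy"), each = 30)
  prov <- rep(c("real-phantom", "synthetic"), 30)
  fold <- withr::with_seed(1, ctGAN3D:::stratifiedFolds(labs, prov, 3L))
  expect_true(all(fold %in% 1:3))
  expect_identical(length(fold), 60L)
  # every item in exactly one fold; strata balanced within 1
  for (cl in unique(labs)) for (pv in unique(prov)) {
    counts <- table(fold[labs == cl & prov == pv])
    expect_lte(diff(range(counts)), 1)
  }
})

test_that("ROC/PR machinery equals the pair-counting oracle and pROC", {
  # tiny worked set: perfectly separated
  rc <- rocCurve(c(.9, .8, .4, .2), c(1, 1, 0, 0))
  expect_equal(rc$rocAuc, 1)
  # with one error
  rc2 <- rocCurve(c(.9, .8, .4, .6), c(1, 1, 0, 0))
  expect_equal(rc2$rocAuc, mannWhitneyAuc(c(.9, .8, .4, .6), c(1, 1, 0, 0)))
  # random scores, including ties
  withr::local_seed(9)
  for (i in 1:5) {
    sc <- round(runif(40), 2)
    y <- rbinom(40, 1, 0.5)
    if (length(unique(y)) < 2) next
    rc3 <- rocCurve(sc, y)
    expect_equal(rc3$rocAuc, mannWhitneyAuc(sc, y), tolerance = 1e-12)
    ref <- as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE,
                                          direction = "<")))
    expect_equal(rc3$rocAuc, ref, tolerance = 1e-12)
  }
  # permutation null: shuffled labels give AUC ~ 0.5
  sc <- runif(2000)
  y <- sample(rep(0:1, 1000))
  expect_lt(abs(rocCurve(sc, y)$rocAuc - 0.5), 0.03)
  expect_error(rocCurve(sc, rep(1, 2000)), "both classes")
})

test_that("grid search trains, refits, and evaluation builds curves", {
  cohort <- makeLabeledCohort(9L, 9L, smallPhantomConfig(71L))
  cfg <- tinyClassifierConfig(epochs = 2L)
  grid <- data.frame(batchSize = c(6L, 9L), learningRate = c(1e-3, 1e-3))
  fit <- trainClassifier(cohort, cfg, kFolds = 3L, grid = grid)
  expect_identical(nrow(fit$foldMetrics), 6L)      # 2 grid points x 3 folds
  expect_true(fit$best$batchSize %in% grid$batchSize)
  ev <- evaluateClassifier(fit$model, cohort)
  expect_s4_class(ev, "EvalCurves")
  expect_true(ev@rocAuc >= 0 && ev@rocAuc <= 1)
  expect_identical(sum(ev@confusion), 18L)
  expect_error(evaluateClassifier(fit$model,
                                  makeLabeledCohort(0L, 4L,
                                                    smallPhantomConfig(72L))),
               "single-class")
})
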