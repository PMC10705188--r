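# ------------------------------------------------------------------------
# The 3D CNN tumor-vs-healthy classifier and its experimental protocol:
# stratified hold-out, synthetic-augmentation training-set assembly,
# random-rotation augmentation, grid search with stratified k-fold CV, and
# ROC/PR evaluation.
# ------------------------------------------------------------------------

#' Classifier configuration
#'
#' Four Conv3D-MaxPool-BatchNorm blocks with 3x3x3 kernels, a dense layer,
#' dropout and a 2-neuron sigmoid output. Paper-scale defaults: 64^3 input,
#' channel progression 64/128/256/512, dense width 512; the grid-search
#' space was batch sizes \{8, 12, 16\} and learning rates
#' \{1e-3, 1e-4, 1e-5\} (see [classifierGrid()]).
#'
#' @param side input cube side; must be divisible by 2^4 (four poolings).
#' @param channels conv channel progression (length 4).
#' @param denseWidth width of the fully connected layer.
#' @param dropout dropout rate in [0, 1).
#' @param batchSize minibatch size.
#' @param learningRate Adam learning rate.
#' @param epochs training epochs.
#' @param seed integer seed.
#' @return A validated list of class `ClassifierConfig`.
#' @export
classifierConfig <- function(side = 64L, channels = c(64L, 128L, 256L, 512L),
                             denseWidth = 512L, dropout = 0.2,
                             batchSize = 8L, learningRate = 1e-3,
                             epochs = 10L, seed = 1L) {
  side <- as.integer(side)
  if (side %% 16L != 0L)
    stop("side must be divisible by 2^4 for the four pooling stages",
         call. = FALSE)
  if (length(channels) != 4L) stop("channels must have length 4", call. = FALSE)
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)", call. = FALSE)
  structure(list(side = side, channels = as.integer(channels),
                 denseWidth = as.integer(denseWidth), dropout = dropout,
                 batchSize = as.integer(batchSize),
                 learningRate = learningRate, epochs = as.integer(epochs),
                 seed = as.integer(seed)),
            class = "ClassifierConfig")
}

#' The grid-search space of the classifier protocol
#' @return data.frame of 9 (batchSize, learningRate) combinations.
#' @export
classifierGrid <- function() {
  expand.grid(batchSize = c(8L, 12L, 16L),
              learningRate = c(1e-3, 1e-4, 1e-5))
}

#' Stratified per-class hold-out split
#'
#' Samples `round(fraction * class size)` items per class (round-half-up,
#' which reproduces the 35/51 test split from a 174/254 cohort at 20%)
#' into the test set, without replacement; the remainder is the training
#' set. Synthetic items never enter the test set: class sizes and sampling
#' are over real-provenance items, with synthetic items (if present)
#' retained in the training partition.
#'
#' @param dataset a [ClassifierDataset-class].
#' @param fraction test fraction in (0, 1).
#' @param seed sampling seed.
#' @return list with `train` and `test` [ClassifierDataset-class] objects
#'   (disjoint, exhaustive).
#' @export
splitHoldout <- function(dataset, fraction = 0.2, seed = 1L) {
  stopifnot(is(dataset, "ClassifierDataset"))
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must be in (0, 1)", call. = FALSE)
  labs <- as.character(datasetLabels(dataset))
  real <- provenance(dataset) != "synthetic"
  testIdx <- integer(0)
  withSeed(seed, {
    for (cl in c("healthy", "tumor")) {
      clIdx <- which(labs == cl & real)
      if (length(clIdx) == 0L)
        stop("class '", cl, "' absent from the dataset", call. = FALSE)
      nTest <- floor(fraction * length(clIdx) + 0.5)   # round half up
      if (nTest == 0L)
        stop("fraction ", fraction, " rounds to an empty test set for ",
             "class '", cl, "'", call. = FALSE)
      testIdx <- c(testIdx, sample(clIdx, nTest))
    }
  })
  testIdx <- sort(testIdx)
  subsetDataset <- function(idx)
    ClassifierDataset(dataset@volumes[idx],
                      as.character(dataset@labels)[idx],
                      dataset@provenance[idx])
  list(train = subsetDataset(setdiff(seq_along(labs), testIdx)),
       test = subsetDataset(testIdx))
}

#' Assemble a training configuration with or without synthetic data
#'
#' Mode `"I"` returns the real training set unchanged; mode `"II"` appends
#' the requested numbers of synthetic tumor and healthy volumes with
#' `provenance = "synthetic"`. At paper scale, mode II adds 114 synthetic
#' tumors and 50 synthetic healthy cubes to the 139/203 real split,
#' balancing both classes at 253.
#'
#' @param trainReal a [ClassifierDataset-class] of real training items.
#' @param synthTumor,synthHealthy [PatchSet-class] objects or lists of
#'   cubes matching the dataset side.
#' @param mode `"I"` or `"II"`.
#' @param nSynthTumor,nSynthHealthy counts to append in mode II (defaults:
#'   all supplied items).
#' @return A [ClassifierDataset-class].
#' @export
assembleConfig <- function(trainReal, synthTumor = NULL, synthHealthy = NULL,
                           mode = c("I", "II"),
                           nSynthTumor = NULL, nSynthHealthy = NULL) {
  stopifnot(is(trainReal, "ClassifierDataset"))
  mode <- match.arg(mode)
  if (mode == "I") return(trainReal)
  asList <- function(x) {
    if (is.null(x)) list() else if (is(x, "PatchSet")) patches(x) else x
  }
  st <- asList(synthTumor); sh <- asList(synthHealthy)
  nT <- nSynthTumor %||% length(st)
  nH <- nSynthHealthy %||% length(sh)
  if (nT > length(st) || nH > length(sh))
    stop("requested synthetic count exceeds supply (", nT, "/", nH,
         " vs ", length(st), "/", length(sh), ")", call. = FALSE)
  ClassifierDataset(
    c(trainReal@volumes, st[seq_len(nT)], sh[seq_len(nH)]),
    c(as.character(trainReal@labels),
      rep("tumor", nT), rep("healthy", nH)),
    c(trainReal@provenance, rep("synthetic", nT + nH)))
}

#' One random rotation augmentation
#'
#' Rotates a volume about one uniformly chosen axis by an angle drawn
#' uniformly from \{5, 10, 20, 40\} degrees with a uniformly random
#' direction (sign), trilinear interpolation, fill -1. Deterministic for a
#' fixed seed.
#'
#' @param volume normalized cube (3D array).
#' @param seed RNG seed.
#' @return rotated cube of identical shape.
#' @export
augmentRandomRotation <- function(volume, seed = 1L) {
  stopifnot3d(volume, "volume")
  withSeed(seed, {
    axis <- sample.int(3L, 1L)
    angle <- sample(c(5, 10, 20, 40), 1L)
    sign <- sample(c(-1, 1), 1L)
    out <- rotateCube(volume, axis, sign * angle, fill = -1)
    out[out < -1] <- -1; out[out > 1] <- 1
    out
  })
}

#' Build the 3D CNN classifier
#'
#' Four Conv3D(3x3x3, same padding, ReLU) -> MaxPool(2) -> BatchNorm
#' blocks, flatten, dense layer, dropout, and a 2-neuron dense sigmoid
#' output. The positive-class (tumor) score is the second neuron's output.
#' The parameter count is reported in the model list.
#'
#' Weights are initialized from the RNG state at call time; wrap in a
#' seeded context (as [trainClassifier()] does) for reproducible builds.
#'
#' @param config a [classifierConfig()].
#' @return a sequential model list with `paramCount`.
#' @export
buildClassifier <- function(config) {
  stopifnot(inherits(config, "ClassifierConfig"))
  s <- config$side
  layers <- list()
  inCh <- 1L
  dim <- s
  for (b in 1:4) {
    ch <- config$channels[b]
    layers[[paste0("conv", b)]] <- makeConv3d(dim, inCh, ch, k = 3L,
                                              stride = 1L,
                                              activation = "relu")
    layers[[paste0("pool", b)]] <- makePool3d(dim, ch)
    dim <- dim %/% 2L
    layers[[paste0("bn", b)]] <- makeBatchNorm(ch)
    inCh <- ch
  }
  layers[["flatten"]] <- makeFlatten(dim^3, inCh)
  layers[["dense"]] <- makeDense(dim^3 * inCh, config$denseWidth,
                                 activation = "relu")
  layers[["dropout"]] <- makeDropout(config$dropout)
  layers[["out"]] <- makeDense(config$denseWidth, 2L,
                               activation = "sigmoid")
  net <- list(kind = "seq", side = s, layers = layers, config = config)
  net$paramCount <- netParamCount(net)
  net
}

# one training run over a fixed item list; returns the fitted model
fitClassifier <- function(volumes, y, config, augment = FALSE) {
  n <- length(volumes)
  model <- buildClassifier(config)
  state <- adamInit(model)
  t <- 0L
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    nb <- max(1L, n %/% config$batchSize)
    for (bi in seq_len(nb)) {
      idx <- ord[((bi - 1L) * config$batchSize + 1L):
                   min(bi * config$batchSize, n)]
      B <- length(idx)
      vols <- volumes[idx]
      if (augment)
        vols <- lapply(vols, function(v)
          augmentRandomRotation(v, seed = sample.int(2^30, 1L)))
      x <- stackCubes(vols)
      fw <- seqForward(model, x, training = TRUE)
      model <- fw$net
      p <- pmin(pmax(fw$out[, 2L], 1e-7), 1 - 1e-7)
      # BCE on the positive-class neuron; sigmoid grad folds to (p - y)/B
      dy <- matrix(0, B, 2L)
      dy[, 2L] <- (p - y[idx]) / (B * p * (1 - p))
      bw <- seqBackward(model, fw$caches, dy)
      st <- adamStep(model, bw$grads, state, config$learningRate,
                     t <- t + 1L, beta1 = 0.9)
      model <- st$net; state <- st$state
      if (!is.finite(sum(p)))
        stop("non-finite classifier loss", call. = FALSE)
    }
  }
  model
}

#' Predict tumor probabilities
#'
#' @param model a fitted classifier from [trainClassifier()] /
#'   [buildClassifier()].
#' @param volumes list of cubes or a [ClassifierDataset-class].
#' @param batchSize forward batch size.
#' @return numeric vector of positive-class (tumor) scores in (0, 1).
#' @export
predictClassifier <- function(model, volumes, batchSize = 16L) {
  if (is(volumes, "ClassifierDataset")) volumes <- datasetVolumes(volumes)
  n <- length(volumes)
  out <- numeric(n)
  done <- 0L
  while (done < n) {
    B <- min(batchSize, n - done)
    fw <- seqForward(model, stackCubes(volumes[done + seq_len(B)]),
                     training = FALSE)
    out[done + seq_len(B)] <- fw$out[, 2L]
    done <- done + B
  }
  out
}

# stratified fold assignment: by class and, within class, by provenance,
# so the synthetic fraction is constant across folds
stratifiedFolds <- function(labels, provenance, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) for (pv in unique(provenance)) {
    idx <- which(labels == cl & provenance == pv)
    if (length(idx) == 0L) next
    idx <- sample(idx)
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Train the classifier with grid search and stratified k-fold CV
#'
#' For every grid point, runs stratified k-fold cross-validation (folds
#' stratified by class and, within class, by provenance), scores mean
#' validation accuracy at threshold 0.5, picks the best grid point, and
#' refits on the full training set. All randomness is seeded from
#' `config$seed`. Aborts naming the grid point if a loss turns non-finite.
#'
#' @param dataset a [ClassifierDataset-class] (>= kFolds items per class).
#' @param config a [classifierConfig()]; its batchSize/learningRate are
#'   used when `grid` is `NULL`.
#' @param kFolds number of CV folds (default 3).
#' @param grid data.frame with columns `batchSize`, `learningRate`
#'   ([classifierGrid()] gives the full 9-point space); `NULL` for the
#'   single configured point.
#' @param augment apply one random rotation per volume per epoch.
#' @return list with `model` (refit on all data), `cvAccuracy` (best grid
#'   point's mean), `foldMetrics` (per grid point x fold accuracies),
#'   `best` (chosen grid row), `paramCount`.
#' @export
trainClassifier <- function(dataset, config, kFolds = 3L, grid = NULL,
                            augment = FALSE) {
  stopifnot(is(dataset, "ClassifierDataset"))
  labs <- as.character(datasetLabels(dataset))
  if (any(table(factor(labs, c("healthy", "tumor"))) < kFolds))
    stop("need at least kFolds items per class", call. = FALSE)
  if (is.null(grid))
    grid <- data.frame(batchSize = config$batchSize,
                       learningRate = config$learningRate)
  y <- as.numeric(labs == "tumor")
  vols <- datasetVolumes(dataset)
  withSeed(config$seed, {
    fold <- stratifiedFolds(labs, provenance(dataset), kFolds)
    foldMetrics <- data.frame()
    means <- numeric(nrow(grid))
    for (gi in seq_len(nrow(grid))) {
      cfg <- config
      cfg$batchSize <- as.integer(grid$batchSize[gi])
      cfg$learningRate <- grid$learningRate[gi]
      accs <- numeric(kFolds)
      for (f in seq_len(kFolds)) {
        tr <- which(fold != f); va <- which(fold == f)
        model <- tryCatch(
          fitClassifier(vols[tr], y[tr], cfg, augment = augment),
          error = function(e)
            stop("grid point (batchSize=", cfg$batchSize, ", lr=",
                 cfg$learningRate, "): ", conditionMessage(e),
                 call. = FALSE))
        p <- predictClassifier(model, vols[va])
        accs[f] <- mean((p >= 0.5) == (y[va] == 1))
      }
      means[gi] <- mean(accs)
      foldMetrics <- rbind(foldMetrics,
                           data.frame(batchSize = cfg$batchSize,
                                      learningRate = cfg$learningRate,
                                      fold = seq_len(kFolds),
                                      accuracy = accs))
    }
    bestIdx <- which.max(means)
    cfg <- config
    cfg$batchSize <- as.integer(grid$batchSize[bestIdx])
    cfg$learningRate <- grid$learningRate[bestIdx]
    model <- fitClassifier(vols, y, cfg, augment = augment)
    list(model = model, cvAccuracy = means[bestIdx],
         cvSd = sd(foldMetrics$accuracy[
           foldMetrics$batchSize == cfg$batchSize &
             foldMetrics$learningRate == cfg$learningRate]),
         foldMetrics = foldMetrics, best = grid[bestIdx, , drop = FALSE],
         paramCount = model$paramCount)
  })
}

#' ROC curve, PR curve and AUCs from scores and labels
#'
#' Threshold sweep over the unique scores: at each threshold a sample is
#' called positive when its score is >= the threshold. AUCs by the
#' trapezoidal rule. Ties in scores are handled by the sweep construction
#' (both members move together), which makes the ROC-AUC equal to the
#' Mann-Whitney U normalization with half-weight ties.
#'
#' @param scores numeric scores (higher = more tumor-like).
#' @param labels 0/1, logical, or factor with positive level `"tumor"`.
#' @return list with `roc`, `pr` data.frames and `rocAuc`, `prAuc`.
#' @export
rocCurve <- function(scores, labels) {
  y <- if (is.factor(labels)) as.numeric(labels == "tumor")
       else as.numeric(labels != 0)
  if (length(unique(y)) < 2L)
    stop("ROC undefined: need both classes in the labels", call. = FALSE)
  P <- sum(y == 1); N <- sum(y == 0)
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- fpr <- prec <- numeric(length(th))
  for (i in seq_along(th)) {
    pos <- scores >= th[i]
    tp <- sum(pos & y == 1); fp <- sum(pos & y == 0)
    tpr[i] <- tp / P
    fpr[i] <- fp / N
    prec[i] <- if (tp + fp > 0) tp / (tp + fp) else 1
  }
  roc <- data.frame(threshold = c(Inf, th), fpr = c(0, fpr),
                    tpr = c(0, tpr))
  if (tail(roc$fpr, 1) < 1 || tail(roc$tpr, 1) < 1)
    roc <- rbind(roc, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  rocAuc <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
  pr <- data.frame(threshold = th, recall = tpr, precision = prec)
  pr <- rbind(data.frame(threshold = Inf, recall = 0, precision = prec[1]),
              pr)
  prAuc <- sum(diff(pr$recall) *
                 (head(pr$precision, -1) + tail(pr$precision, -1)) / 2)
  list(roc = roc, pr = pr, rocAuc = rocAuc, prAuc = prAuc)
}

#' Evaluate a classifier on a test set
#'
#' Scores the test volumes, builds ROC and PR curves by threshold sweep,
#' computes both AUCs by the trapezoidal rule and the confusion matrix at
#' threshold 0.5. The test set must contain both classes.
#'
#' @param model a fitted classifier.
#' @param test a non-empty [ClassifierDataset-class].
#' @return An [EvalCurves-class].
#' @export
evaluateClassifier <- function(model, test) {
  stopifnot(is(test, "ClassifierDataset"))
  if (length(test) == 0L) stop("empty test set", call. = FALSE)
  y <- as.numeric(datasetLabels(test) == "tumor")
  if (length(unique(y)) < 2L)
    stop("single-class test set: ROC undefined", call. = FALSE)
  scores <- predictClassifier(model, test)
  rc <- rocCurve(scores, y)
  pos <- scores >= 0.5
  conf <- c(TP = sum(pos & y == 1), FP = sum(pos & y == 0),
            TN = sum(!pos & y == 0), FN = sum(!pos & y == 1))
  new("EvalCurves", roc = rc$roc, pr = rc$pr, rocAuc = rc$rocAuc,
      prAuc = rc$prAuc, confusion = conf)
}
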