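# ------------------------------------------------------------------------
# The 3D U-Net GAN: generator (stride-2 3x3x3 encoder, transposed-conv
# decoder with skip concatenation, tanh output), 3-block CNN discriminator,
# adversarial losses, seeded training loop with periodic checkpoints,
# pre-collapse checkpoint selection, and synthesis.
# ------------------------------------------------------------------------

#' GAN configuration
#'
#' Architecture and schedule parameters of the volumetric GAN. At paper
#' scale the tumor model uses `side = 32` and the pancreas model
#' `side = 64`, trained for 2000 epochs with checkpoints every 20; the
#' package defaults keep those values. The training grid explored batch
#' sizes \{4, 8, 16, 32\} and learning rates \{1e-1 ... 1e-5\}; both are
#' plain fields here so a grid driver can sweep them.
#'
#' @param side cube side in voxels; must be divisible by `2^unetDepth`.
#' @param unetDepth number of stride-2 encoder/decoder levels.
#' @param baseChannels channels of the first encoder level; level l uses
#'   `baseChannels * 2^(l-1)` (capped at 8x base).
#' @param learningRate Adam learning rate shared by both networks.
#' @param batchSize minibatch size.
#' @param epochs training epochs (paper scale 2000).
#' @param checkpointInterval epochs between checkpoints (paper scale 20).
#' @param nonSaturating if `TRUE` the generator minimizes
#'   `-mean(log D(G(z)))` instead of the saturating `mean(log(1 - D(G(z))))`.
#' @param beta1,beta2 Adam moment decay rates.
#' @param seed integer seed; fully determines training.
#' @return A validated list of class `GANConfig`.
#' @export
ganConfig <- function(side = 32L, unetDepth = 4L, baseChannels = 32L,
                      learningRate = 1e-4, batchSize = 4L, epochs = 2000L,
                      checkpointInterval = 20L, nonSaturating = FALSE,
                      beta1 = 0.5, beta2 = 0.999, seed = 1L) {
  side <- as.integer(side); unetDepth <- as.integer(unetDepth)
  if (side %% (2L^unetDepth) != 0L)
    stop("side must be divisible by 2^unetDepth", call. = FALSE)
  if (epochs < checkpointInterval || checkpointInterval < 1L)
    stop("need epochs >= checkpointInterval >= 1", call. = FALSE)
  structure(list(side = side, unetDepth = unetDepth,
                 baseChannels = as.integer(baseChannels),
                 learningRate = learningRate,
                 batchSize = as.integer(batchSize),
                 epochs = as.integer(epochs),
                 checkpointInterval = as.integer(checkpointInterval),
                 nonSaturating = isTRUE(nonSaturating),
                 beta1 = beta1, beta2 = beta2, seed = as.integer(seed)),
            class = "GANConfig")
}

ganLevelChannels <- function(config) {
  pmin(config$baseChannels * 2L^(seq_len(config$unetDepth) - 1L),
       8L * config$baseChannels)
}

#' Build the 3D U-Net generator
#'
#' Encoder: `unetDepth` stride-2 3x3x3 convolutions with ReLU. Decoder:
#' mirrored stride-2 transposed 3x3x3 convolutions; each decoder level is
#' concatenated with the matching encoder level (skip connection). A final
#' 3x3x3 single-channel convolution with tanh maps to the normalized
#' intensity domain, so outputs lie strictly inside (-1, 1). The generator
#' consumes a single-channel i.i.d. standard-normal noise grid of the same
#' spatial size as the output, keeping the network fully convolutional.
#'
#' Weights are initialized from the RNG state at call time; wrap in a
#' seeded context (as [trainGan()] does) for reproducible builds.
#'
#' @param config a [ganConfig()].
#' @return A generator model list (`kind = "unet"`) with a `paramCount`.
#' @export
buildGenerator <- function(config) {
  stopifnot(inherits(config, "GANConfig"))
  s <- config$side; D <- config$unetDepth
  ch <- ganLevelChannels(config)
  layers <- list()
  inCh <- 1L
  for (l in seq_len(D)) {
    layers[[paste0("enc", l)]] <-
      makeConv3d(s / 2L^(l - 1L), inCh, ch[l], k = 3L, stride = 2L,
                 activation = "relu")
    inCh <- ch[l]
  }
  # decoder step t maps side/2^(D-t+1) -> side/2^(D-t)
  prevCh <- ch[D]
  for (t in seq_len(D)) {
    lev <- D - t + 1L                       # encoder level being undone
    inC <- if (t == 1L) prevCh else prevCh + ch[lev]
    outC <- if (lev == 1L) config$baseChannels else ch[lev - 1L]
    layers[[paste0("dec", t)]] <-
      makeConvT3d(s / 2L^lev, inC, outC, activation = "relu")
    prevCh <- outC
  }
  layers[["final"]] <- makeConv3d(s, prevCh, 1L, k = 3L, stride = 1L,
                                  activation = "tanh")
  gen <- list(kind = "unet", side = s, depth = D, channels = ch,
              layers = layers)
  gen$paramCount <- netParamCount(gen)
  gen
}

ganGeneratorForward <- function(gen, z, training = FALSE) {
  D <- gen$depth
  caches <- list()
  enc <- vector("list", D)
  x <- z
  for (l in seq_len(D)) {
    fw <- layerForward(gen$layers[[paste0("enc", l)]], x, training)
    x <- fw$y; caches[[paste0("enc", l)]] <- fw$cache
    gen$layers[[paste0("enc", l)]] <- fw$layer
    enc[[l]] <- x
  }
  concatCh <- integer(D)
  for (t in seq_len(D)) {
    lev <- D - t + 1L
    if (t > 1L) {
      concatCh[t] <- dim(x)[2]              # channels from previous decoder
      x <- abind2(x, enc[[lev]])
    }
    fw <- layerForward(gen$layers[[paste0("dec", t)]], x, training)
    x <- fw$y; caches[[paste0("dec", t)]] <- fw$cache
    gen$layers[[paste0("dec", t)]] <- fw$layer
  }
  fw <- layerForward(gen$layers[["final"]], x, training)
  caches[["final"]] <- fw$cache
  gen$layers[["final"]] <- fw$layer
  list(out = fw$y, caches = caches, concatCh = concatCh, gen = gen)
}

# concatenate two activation arrays along the channel axis
abind2 <- function(a, b) {
  out <- array(0, c(dim(a)[1], dim(a)[2] + dim(b)[2], dim(a)[3]))
  out[, seq_len(dim(a)[2]), ] <- a
  out[, dim(a)[2] + seq_len(dim(b)[2]), ] <- b
  out
}

ganGeneratorBackward <- function(gen, fwd, dout) {
  D <- gen$depth
  grads <- list()
  bw <- layerBackward(gen$layers[["final"]], fwd$caches[["final"]], dout)
  grads[["final"]] <- bw$grads
  dy <- bw$dx
  dEnc <- vector("list", D)                  # skip-connection gradients
  for (t in rev(seq_len(D))) {
    lev <- D - t + 1L
    bw <- layerBackward(gen$layers[[paste0("dec", t)]],
                        fwd$caches[[paste0("dec", t)]], dy)
    grads[[paste0("dec", t)]] <- bw$grads
    dy <- bw$dx
    if (t > 1L) {
      nPrev <- fwd$concatCh[t]
      dEnc[[lev]] <- dy[, (nPrev + 1L):dim(dy)[2], , drop = FALSE]
      dy <- dy[, seq_len(nPrev), , drop = FALSE]
    }
  }
  for (l in rev(seq_len(D))) {
    if (!is.null(dEnc[[l]])) dy <- dy + dEnc[[l]]
    bw <- layerBackward(gen$layers[[paste0("enc", l)]],
                        fwd$caches[[paste0("enc", l)]], dy)
    grads[[paste0("enc", l)]] <- bw$grads
    dy <- bw$dx
  }
  grads
}

#' Build the 3D CNN discriminator
#'
#' Three blocks of (2x2x2 convolution, stride 1, ReLU) -> (max-pool 2) ->
#' (batch normalization), then flatten and one fully connected layer with a
#' sigmoid, so any input maps to a scalar in (0, 1).
#'
#' @param config a [ganConfig()].
#' @return A sequential model list.
#' @export
buildDiscriminator <- function(config) {
  stopifnot(inherits(config, "GANConfig"))
  s <- config$side
  if (s < 8L) stop("side must be >= 8 for three pooling stages", call. = FALSE)
  ch <- pmin(config$baseChannels * c(1L, 2L, 4L), 8L * config$baseChannels)
  layers <- list()
  inCh <- 1L
  dim <- s
  for (b in 1:3) {
    layers[[paste0("conv", b)]] <- makeConv3d(dim, inCh, ch[b], k = 2L,
                                              stride = 1L,
                                              activation = "relu")
    layers[[paste0("pool", b)]] <- makePool3d(dim, ch[b])
    dim <- dim %/% 2L
    layers[[paste0("bn", b)]] <- makeBatchNorm(ch[b])
    inCh <- ch[b]
  }
  layers[["flatten"]] <- makeFlatten(dim^3, inCh)
  layers[["out"]] <- makeDense(dim^3 * inCh, 1L, activation = "sigmoid")
  net <- list(kind = "seq", side = s, layers = layers)
  net$paramCount <- netParamCount(net)
  net
}

#' Adversarial losses
#'
#' From discriminator outputs on real and fake batches, returns the
#' generator loss `mean(log(1 - dFake))` (to be minimized; the saturating
#' form) and the discriminator objective
#' `mean(log dReal) + mean(log(1 - dFake))` (to be maximized). Natural
#' logarithms; probabilities are clamped 1e-7 away from 0 and 1.
#'
#' @param dReal,dFake numeric vectors of probabilities in (0, 1).
#' @return list with `generatorLoss` and `discriminatorObjective`.
#' @export
adversarialLosses <- function(dReal, dFake) {
  if (length(dReal) == 0L || length(dFake) == 0L)
    stop("empty batch", call. = FALSE)
  dReal <- pmin(pmax(dReal, 1e-7), 1 - 1e-7)
  dFake <- pmin(pmax(dFake, 1e-7), 1 - 1e-7)
  list(generatorLoss = mean(log(1 - dFake)),
       discriminatorObjective = mean(log(dReal)) + mean(log(1 - dFake)))
}

ganGetParams <- function(model) lapply(model$layers, `[[`, "params")

ganSetParams <- function(model, params) {
  for (nm in names(params)) model$layers[[nm]]$params <- params[[nm]]
  model
}

addGrads <- function(a, b) {
  for (i in seq_along(a))
    for (nm in names(a[[i]])) a[[i]][[nm]] <- a[[i]][[nm]] + b[[i]][[nm]]
  a
}

#' Train the GAN
#'
#' Alternating one-discriminator-step / one-generator-step updates per
#' minibatch with Adam. Checkpoints (generator weights + config + seed +
#' epoch) are recorded at every multiple of `checkpointInterval`. Fully
#' reproducible given `config$seed`. Aborts with the offending epoch if a
#' loss becomes non-finite.
#'
#' @param train a [PatchSet-class]; all patches must have `config$side`.
#' @param config a [ganConfig()].
#' @param verbose print a progress line every 50 epochs.
#' @return A [TrainLog-class].
#' @export
trainGan <- function(train, config, verbose = FALSE) {
  stopifnot(is(train, "PatchSet"), inherits(config, "GANConfig"))
  n <- length(train)
  if (n == 0L) stop("empty training set", call. = FALSE)
  if (patchSide(train) != config$side)
    stop("patch side ", patchSide(train), " does not match config side ",
         config$side, call. = FALSE)
  if (config$batchSize > n)
    stop("batchSize exceeds training-set size", call. = FALSE)
  withSeed(config$seed, {
    gen <- buildGenerator(config)
    dis <- buildDiscriminator(config)
    adamG <- adamInit(gen)
    adamD <- adamInit(dis)
    nVox <- config$side^3
    cubes <- patches(train)
    gLossEp <- dLossEp <- numeric(config$epochs)
    checkpoints <- list()
    tG <- tD <- 0L
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      nb <- n %/% config$batchSize
      gAcc <- dAcc <- 0
      for (bi in seq_len(nb)) {
        idx <- ord[((bi - 1L) * config$batchSize + 1L):(bi * config$batchSize)]
        B <- length(idx)
        real <- stackCubes(cubes[idx])
        z <- array(rnorm(nVox * B), c(nVox, 1L, B))
        # --- discriminator step ---
        gf <- ganGeneratorForward(gen, z, training = TRUE)
        gen <- gf$gen
        fake <- gf$out
        fwR <- seqForward(dis, real, training = TRUE)
        dis <- fwR$net
        pR <- pmin(pmax(as.vector(fwR$out), 1e-7), 1 - 1e-7)
        fwF <- seqForward(dis, fake, training = TRUE)
        dis <- fwF$net
        pF <- pmin(pmax(as.vector(fwF$out), 1e-7), 1 - 1e-7)
        # minimize -(mean log pR + mean log(1 - pF))
        dyR <- matrix(-1 / (B * pR), B, 1L)
        dyF <- matrix(1 / (B * (1 - pF)), B, 1L)
        bwR <- seqBackward(dis, fwR$caches, dyR)
        bwF <- seqBackward(dis, fwF$caches, dyF)
        st <- adamStep(dis, addGrads(bwR$grads, bwF$grads), adamD,
                       config$learningRate, tD <- tD + 1L,
                       config$beta1, config$beta2)
        dis <- st$net; adamD <- st$state
        # --- generator step (through the updated discriminator) ---
        gf <- ganGeneratorForward(gen, z, training = TRUE)
        gen <- gf$gen
        fwF2 <- seqForward(dis, gf$out, training = TRUE)
        dis <- fwF2$net
        pF2 <- pmin(pmax(as.vector(fwF2$out), 1e-7), 1 - 1e-7)
        dyG <- if (config$nonSaturating)
          matrix(-1 / (B * pF2), B, 1L)          # -mean log pF
        else
          matrix(-1 / (B * (1 - pF2)), B, 1L)    # mean log(1 - pF)
        bwD <- seqBackward(dis, fwF2$caches, dyG)
        gGrads <- ganGeneratorBackward(gen, gf, bwD$dx)
        st <- adamStep(gen, gGrads[names(gen$layers)], adamG,
                       config$learningRate, tG <- tG + 1L,
                       config$beta1, config$beta2)
        gen <- st$net; adamG <- st$state
        losses <- adversarialLosses(pR, pF2)
        gAcc <- gAcc + (if (config$nonSaturating) -mean(log(pF2))
                        else losses$generatorLoss)
        dAcc <- dAcc + losses$discriminatorObjective
      }
      gLossEp[epoch] <- gAcc / nb
      dLossEp[epoch] <- dAcc / nb
      if (!is.finite(gLossEp[epoch]) || !is.finite(dLossEp[epoch]))
        stop("non-finite loss at epoch ", epoch, call. = FALSE)
      if (epoch %% config$checkpointInterval == 0L)
        checkpoints[[as.character(epoch)]] <-
          list(epoch = epoch, config = config, seed = config$seed,
               params = ganGetParams(gen))
      if (verbose && epoch %% 50L == 0L)
        message(sprintf("epoch %d: G %.4f D %.4f", epoch,
                        gLossEp[epoch], dLossEp[epoch]))
    }
    new("TrainLog", epochs = seq_len(config$epochs), gLoss = gLossEp,
        dLoss = dLossEp, checkpoints = checkpoints,
        config = unclass(config), seed = config$seed)
  })
}

#' Select the last good checkpoint before a loss spike
#'
#' GAN collapse shows up as a drastic rise of the generator loss. The
#' per-epoch generator loss is smoothed with a centered moving average of
#' `window` epochs and compared, at each checkpoint, against the
#' first-quartile smoothed loss times `spikeFactor` (applied on the loss
#' magnitude, so negative-valued saturating-loss curves are handled
#' symmetrically). Returns the latest checkpointed epoch before the first
#' spike, or the final checkpoint if no spike exists.
#'
#' @param log a [TrainLog-class].
#' @param spikeFactor multiplicative spike threshold (default 3).
#' @param window smoothing window in epochs (default 5).
#' @return the selected epoch (integer).
#' @export
selectCheckpoint <- function(log, spikeFactor = 3, window = 5L) {
  stopifnot(is(log, "TrainLog"))
  cps <- sort(as.integer(names(log@checkpoints)))
  if (length(cps) == 0L) stop("log has no checkpoints", call. = FALSE)
  x <- log@gLoss
  n <- length(x)
  half <- window %/% 2L
  smoothed <- vapply(seq_len(n), function(i)
    mean(x[max(1L, i - half):min(n, i + half)]), 0)
  q1 <- quantile(smoothed, 0.25, names = FALSE)
  threshold <- if (q1 >= 0) q1 * spikeFactor else q1 / spikeFactor
  atCp <- smoothed[cps]
  spiked <- which(atCp > threshold)
  if (length(spiked) == 0L) return(cps[length(cps)])
  if (spiked[1] == 1L) {
    warning("loss spike before the first checkpoint; returning it anyway")
    return(cps[1])
  }
  cps[spiked[1] - 1L]
}

#' Synthesize patches from a checkpoint
#'
#' Rebuilds the generator from the stored weights and runs it on seeded
#' standard-normal noise grids. Deterministic for a fixed seed; `n = 0`
#' returns an empty set.
#'
#' @param checkpoint a checkpoint from a [TrainLog-class]
#'   (`log@checkpoints[[i]]`), or a path to an RDS file containing one.
#' @param n number of volumes to synthesize.
#' @param seed RNG seed for the noise.
#' @param tissueClass tissue label for the returned set.
#' @param batchSize forward batch size.
#' @return A [PatchSet-class] of `n` patches with values in (-1, 1),
#'   provenance `"synthetic"`.
#' @export
synthesize <- function(checkpoint, n, seed = 1L, tissueClass = "tumor",
                       batchSize = 16L) {
  if (is.character(checkpoint)) {
    if (!file.exists(checkpoint))
      stop("missing checkpoint file: ", checkpoint, call. = FALSE)
    checkpoint <- readRDS(checkpoint)
  }
  if (!is.list(checkpoint) || is.null(checkpoint$params))
    stop("not a checkpoint object", call. = FALSE)
  config <- checkpoint$config
  if (!inherits(config, "GANConfig")) class(config) <- "GANConfig"
  n <- as.integer(n)
  if (n == 0L)
    return(PatchSet(list(), tissueClass = tissueClass,
                    provenance = "synthetic"))
  withSeed(seed, {
    gen <- ganSetParams(buildGenerator(config), checkpoint$params)
    nVox <- config$side^3
    out <- vector("list", n)
    done <- 0L
    while (done < n) {
      B <- min(batchSize, n - done)
      z <- array(rnorm(nVox * B), c(nVox, 1L, B))
      fw <- ganGeneratorForward(gen, z, training = FALSE)
      cubes <- unstackCubes(fw$out, rep(config$side, 3L))
      for (b in seq_len(B)) out[[done + b]] <- cubes[[b]]
      done <- done + B
    }
    PatchSet(out, tissueClass = tissueClass, provenance = "synthetic",
             sourceIds = sprintf("synth-%04d", seq_len(n)))
  })
}

#' Save a checkpoint to disk
#' @param checkpoint a checkpoint object from a [TrainLog-class].
#' @param path output path (RDS archive of weights + config + seed + epoch).
#' @return `path`, invisibly.
#' @export
saveCheckpoint <- function(checkpoint, path) {
  saveRDS(checkpoint, path)
  invisible(path)
}

#' Write a TrainLog's loss history as CSV
#' @param log a [TrainLog-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeTrainLog <- function(log, path) {
  write.csv(data.frame(epoch = log@epochs, generator_loss = log@gLoss,
                       discriminator_objective = log@dLoss),
            path, row.names = FALSE)
  invisible(path)
}
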