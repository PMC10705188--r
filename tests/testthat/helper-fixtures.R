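# Shared fixture builders: everything is generated in code, seeded, and
# small enough for fast test runs.

smallPhantomConfig <- function(seed = 1L, side = 16L, ...) {
  phantomConfig(sideLength = side, tumorRadiusRange = c(3, 5),
                seed = seed, ...)
}

# normalized phantom tumor patch of the given side
phantomPatch <- function(seed = 1L, side = 16L) {
  voxels(normalizeWindow(makePhantomScan(smallPhantomConfig(seed, side))$volume))
}

# normalized pancreas texture cube
texturePatch <- function(seed = 1L, side = 32L) {
  voxels(normalizeWindow(makeTextureCube(smallPhantomConfig(seed, side))))
}

phantomPatchSet <- function(n, side = 16L, seedBase = 100L,
                            tissueClass = "tumor") {
  PatchSet(lapply(seq_len(n), function(i) phantomPatch(seedBase + i, side)),
           tissueClass = tissueClass, provenance = "real-phantom")
}

noisePatchSet <- function(n, side = 16L, seed = 1L) {
  cubes <- withr::with_seed(seed, lapply(seq_len(n), function(i)
    array(runif(side^3, -1, 1), rep(side, 3L))))
  PatchSet(cubes, tissueClass = "tumor", provenance = "synthetic")
}

tinyGanConfig <- function(side = 16L, epochs = 20L, seed = 5L, ...) {
  ganConfig(side = side, unetDepth = 2L, baseChannels = 4L,
            learningRate = 2e-4, batchSize = 8L, epochs = epochs,
            checkpointInterval = min(20L, epochs), seed = seed, ...)
}

tinyClassifierConfig <- function(seed = 3L, epochs = 6L, ...) {
  classifierConfig(side = 16L, channels = c(4L, 8L, 12L, 16L),
                   denseWidth = 16L, dropout = 0.1, batchSize = 8L,
                   learningRate = 1e-3, epochs = epochs, seed = seed, ...)
}

# Mann-Whitney pair-counting AUC oracle (half weight on ties)
mannWhitneyAuc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
    (length(pos) * length(neg))
}

# numeric central-difference gradient of f at x restricted to indices idx
numericGrad <- function(f, x, idx, h = 1e-5) {
  vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, 0)
}
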