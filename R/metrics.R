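# ------------------------------------------------------------------------
# Image-quality and diversity metrics: Frechet distances over feature
# statistics (slice-wise FID with an offline 2D backend, and the 3D variant
# over a cold-started seeded 3D CNN), slice PSNR, kernel MMD^2, and
# pairwise MS-SSIM diversity.
# ------------------------------------------------------------------------

#' Build the cold-started feature extractor
#'
#' An untrained CNN with four convolutional blocks (3x3x3 kernels for
#' `dims = 3`, 3x3 for the 2D slice backend), ReLU and 2x pooling, channel
#' progression ending at 512, followed by global average pooling so the
#' feature vector has length 512 for any input side >= 16. Weights are
#' drawn once from a seeded RNG (default seed 42) and never updated.
#'
#' @param seed weight-initialization seed (default 42).
#' @param dims 3 for volumes, 2 for the slice-FID backend.
#' @param channels channel progression; must end at 512.
#' @return An extractor object (weights + metadata).
#' @export
buildFeatureExtractor <- function(seed = 42L, dims = 3L,
                                  channels = c(8L, 16L, 32L, 512L)) {
  stopifnot(length(channels) == 4L, tail(channels, 1L) == 512L,
            dims %in% c(2L, 3L))
  kk <- if (dims == 3L) 27L else 9L
  withSeed(seed, {
    weights <- vector("list", 4L)
    inCh <- 1L
    for (b in 1:4) {
      weights[[b]] <- list(
        W = initWeight(kk * inCh, channels[b], kk * inCh, "relu"),
        b = numeric(channels[b]))
      inCh <- channels[b]
    }
    structure(list(kind = "extractor", dims = dims, seed = as.integer(seed),
                   channels = as.integer(channels), weights = weights,
                   untrained = TRUE),
              class = "FeatureExtractor")
  })
}

# instantiate the sequential net of an extractor for a concrete input shape
extractorNet <- function(extractor, inDim) {
  d3 <- extractor$dims == 3L
  k <- if (d3) c(3L, 3L, 3L) else c(3L, 3L, 1L)
  padv <- if (d3) c(1L, 1L, 1L) else c(1L, 1L, 0L)
  poolK <- if (d3) c(2L, 2L, 2L) else c(2L, 2L, 1L)
  layers <- list()
  inCh <- 1L
  dim <- inDim
  for (b in 1:4) {
    cv <- makeConv3d(dim, inCh, extractor$channels[b], k = k,
                     padLo = padv, padHi = padv, activation = "relu")
    cv$params <- extractor$weights[[b]]
    layers[[paste0("conv", b)]] <- cv
    pl <- list(type = "pool3d",
               geom = convGeom(dim, poolK, poolK, 0L, 0L),
               ch = extractor$channels[b], params = list())
    layers[[paste0("pool", b)]] <- pl
    dim <- pl$geom$outDim
    inCh <- extractor$channels[b]
  }
  layers[["gap"]] <- makeGlobalAvgPool(512L)
  list(kind = "seq", layers = layers, outDim = dim)
}

checkExtractorInput <- function(extractor, d) {
  active <- if (extractor$dims == 3L) d else d[1:2]
  if (any(active < 16L))
    stop("extractor input side must be >= 16, got ",
         paste(d, collapse = "x"), call. = FALSE)
}

#' Extract features from a set of volumes or slices
#'
#' @param extractor a [buildFeatureExtractor()] object.
#' @param items list of 3D arrays (or 2D matrices for a 2D extractor) or a
#'   [PatchSet-class].
#' @param batchSize forward batch size.
#' @return numeric matrix, one 512-length feature row per item.
#' @export
extractFeatures <- function(extractor, items, batchSize = 16L) {
  if (is(items, "PatchSet")) items <- patches(items)
  if (length(items) == 0L) stop("no items to extract from", call. = FALSE)
  items <- lapply(items, function(x) {
    if (length(dim(x) %||% 1L) == 2L) x <- array(x, c(dim(x), 1L))
    stopifnot3d(x, "extractor input")
    x
  })
  d <- dim(items[[1]])
  checkExtractorInput(extractor, d)
  net <- extractorNet(extractor, d)
  n <- length(items)
  out <- matrix(0, n, 512L)
  done <- 0L
  while (done < n) {
    B <- min(batchSize, n - done)
    x <- stackCubes(items[done + seq_len(B)])
    fw <- seqForward(net, x, training = FALSE)
    out[done + seq_len(B), ] <- fw$out
    done <- done + B
  }
  out
}

#' Gaussian feature statistics of a feature matrix
#'
#' @param features numeric matrix, one feature row per sample (n >= 2).
#' @return A [FeatureStats-class] (mean vector, covariance, n).
#' @export
featureStats <- function(features) {
  features <- as.matrix(features)
  if (nrow(features) < 2L)
    stop("need at least 2 samples for a covariance", call. = FALSE)
  new("FeatureStats", mu = colMeans(features), sigma = cov(features),
      n = nrow(features))
}

#' Frechet distance between two Gaussian feature summaries
#'
#' \deqn{d^2 = \|\mu_1 - \mu_2\|^2 + \mathrm{Tr}(C_1 + C_2 - 2 (C_1 C_2)^{1/2})}
#' computed through the symmetric eigendecomposition of
#' \eqn{C_1^{1/2} C_2 C_1^{1/2}}. Symmetric in its arguments, zero for
#' identical statistics; a tiny negative numerical residue (>= -1e-6) is
#' clipped to 0. With `printedForm = TRUE` the matrix square root is
#' omitted (`Tr(C1 + C2 - 2 C1 C2)`), a debugging form that does not
#' vanish for identical distributions.
#'
#' @param a,b [FeatureStats-class] objects of matching dimension.
#' @param printedForm omit the matrix square root (debug only).
#' @return squared Frechet distance (scalar).
#' @export
frechetDistance <- function(a, b, printedForm = FALSE) {
  stopifnot(is(a, "FeatureStats"), is(b, "FeatureStats"))
  if (length(a@mu) != length(b@mu))
    stop("feature dimensions differ: ", length(a@mu), " vs ", length(b@mu),
         call. = FALSE)
  meanTerm <- sum((a@mu - b@mu)^2)
  if (printedForm) {
    traceTerm <- sum(diag(a@sigma + b@sigma - 2 * a@sigma %*% b@sigma))
  } else {
    # noisy near-zero eigenvalues of rank-deficient covariances blow up
    # under the square root; zap them relative to the spectral radius
    zap <- function(v) { v[v < max(v, 0) * 1e-10] <- 0; v }
    e1 <- eigen((a@sigma + t(a@sigma)) / 2, symmetric = TRUE)
    s1 <- e1$vectors %*% (sqrt(zap(e1$values)) * t(e1$vectors))
    M <- s1 %*% b@sigma %*% s1
    ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
    traceTerm <- sum(diag(a@sigma)) + sum(diag(b@sigma)) -
      2 * sum(sqrt(zap(ev)))
  }
  d2 <- meanTerm + traceTerm
  if (d2 < 0 && d2 > -1e-6) d2 <- 0
  d2
}

#' Frechet 3D distance (F3D) between two volume sets
#'
#' Features are extracted batch-wise with the cold-started seeded 3D CNN,
#' summarized as Gaussians, and compared with [frechetDistance()].
#' Deterministic given the extractor seed; invariant to the storage order
#' of volumes within each set.
#'
#' @param real,synth [PatchSet-class] objects or lists of cubes (>= 2 each,
#'   uniform sides per set).
#' @param extractor a 3D [buildFeatureExtractor()] (default seed 42).
#' @return squared Frechet distance (scalar >= 0 up to numerics).
#' @export
f3d <- function(real, synth, extractor = buildFeatureExtractor()) {
  fr <- extractFeatures(extractor, real)
  fs <- extractFeatures(extractor, synth)
  frechetDistance(featureStats(fr), featureStats(fs))
}

#' Slice-wise FID on a named anatomical plane
#'
#' Takes each volume's center slice on the requested plane and computes the
#' Frechet distance between the feature statistics of the two slice sets
#' under a 2D feature backend. The default backend is the seeded untrained
#' 2D CNN analogous to the F3D extractor, which runs fully offline;
#' pretrained-backbone FID values from the literature are not comparable
#' across backends, so reports should name the backend used.
#'
#' @param real,synth [PatchSet-class] objects or lists of cubes (>= 2 each).
#' @param plane `"sagittal"`, `"axial"` or `"coronal"`.
#' @param backend a 2D [buildFeatureExtractor()].
#' @return squared Frechet distance of the slice sets.
#' @export
sliceFid <- function(real, synth, plane = "axial",
                     backend = buildFeatureExtractor(dims = 2L)) {
  if (is(real, "PatchSet")) real <- patches(real)
  if (is(synth, "PatchSet")) synth <- patches(synth)
  if (length(real) < 2L || length(synth) < 2L)
    stop("need >= 2 volumes per set", call. = FALSE)
  plane <- match.arg(plane, c("sagittal", "axial", "coronal"))
  sr <- lapply(real, centerSlice, plane = plane)
  ss <- lapply(synth, centerSlice, plane = plane)
  fr <- extractFeatures(backend, sr)
  fs <- extractFeatures(backend, ss)
  frechetDistance(featureStats(fr), featureStats(fs))
}

#' Slice-wise PSNR between two sets
#'
#' Mean over pairs of \eqn{10 \log_{10}(R^2 / \mathrm{MSE})} on center
#' slices, with data range R = 2 for normalized patches. The sets are
#' unpaired in origin, so a pairing policy is required: `"random"` draws a
#' seeded random bijection, `"index"` pairs by position. Identical pairs
#' (zero MSE) are reported at the documented 99 dB cap.
#'
#' @param real,synth equally sized [PatchSet-class] objects or lists.
#' @param plane `"sagittal"`, `"axial"` or `"coronal"`.
#' @param pairing `"random"` or `"index"`.
#' @param seed seed for the random pairing.
#' @param dataRange intensity range R (2 for the normalized domain).
#' @param cap dB value reported for zero-MSE pairs.
#' @return mean PSNR in dB.
#' @export
slicePsnr <- function(real, synth, plane = "axial",
                      pairing = c("random", "index"), seed = 1L,
                      dataRange = 2, cap = 99) {
  if (is(real, "PatchSet")) real <- patches(real)
  if (is(synth, "PatchSet")) synth <- patches(synth)
  pairing <- match.arg(pairing)
  n <- length(real)
  if (length(synth) != n)
    stop("paired PSNR needs equally sized sets (", n, " vs ",
         length(synth), ")", call. = FALSE)
  plane <- match.arg(plane, c("sagittal", "axial", "coronal"))
  perm <- if (pairing == "random") withSeed(seed, sample.int(n)) else seq_len(n)
  vals <- vapply(seq_len(n), function(i) {
    a <- centerSlice(real[[i]], plane)
    b <- centerSlice(synth[[perm[i]]], plane)
    mse <- mean((a - b)^2)
    if (mse == 0) cap else min(cap, 10 * log10(dataRange^2 / mse))
  }, 0)
  mean(vals)
}

#' Squared maximum mean discrepancy between two sample sets
#'
#' Gaussian-RBF kernel MMD^2 with the median-heuristic bandwidth (median
#' pairwise Euclidean distance over the pooled samples) unless overridden.
#' The unbiased estimator (default) needs >= 2 samples per set; the biased
#' estimator is always >= 0. If every point in both sets is identical the
#' bandwidth degenerates and the discrepancy is defined as 0.
#'
#' @param a,b numeric matrices, one sample per row (vectors are treated as
#'   single samples).
#' @param bandwidth kernel bandwidth sigma; `NULL` for the median heuristic.
#' @param unbiased use the unbiased estimator (default `TRUE`).
#' @return MMD^2 estimate (scalar).
#' @export
mmd2 <- function(a, b, bandwidth = NULL, unbiased = TRUE) {
  if (is.null(dim(a))) a <- matrix(a, nrow = 1L)
  if (is.null(dim(b))) b <- matrix(b, nrow = 1L)
  m <- nrow(a); n <- nrow(b)
  if (unbiased && (m < 2L || n < 2L))
    stop("unbiased MMD^2 needs >= 2 samples per set", call. = FALSE)
  pooled <- rbind(a, b)
  d2 <- as.matrix(stats::dist(pooled))^2
  if (is.null(bandwidth)) {
    dists <- sqrt(d2[upper.tri(d2)])
    bandwidth <- median(dists)
  }
  if (bandwidth == 0) return(0)
  K <- exp(-d2 / (2 * bandwidth^2))
  Kaa <- K[seq_len(m), seq_len(m), drop = FALSE]
  Kbb <- K[m + seq_len(n), m + seq_len(n), drop = FALSE]
  Kab <- K[seq_len(m), m + seq_len(n), drop = FALSE]
  if (unbiased) {
    (sum(Kaa) - sum(diag(Kaa))) / (m * (m - 1)) +
      (sum(Kbb) - sum(diag(Kbb))) / (n * (n - 1)) -
      2 * mean(Kab)
  } else {
    mean(Kaa) + mean(Kbb) - 2 * mean(Kab)
  }
}

# ---- SSIM machinery ------------------------------------------------------

# Gaussian-window (11x11, sigma 1.5) SSIM components of two 2D images.
# Returns mean luminance*cs and mean cs (for the multi-scale product).
ssimComponents2d <- function(x, y, dataRange = 2) {
  C1 <- (0.01 * dataRange)^2
  C2 <- (0.03 * dataRange)^2
  sm <- function(m) gaussianSmooth3d(array(m, c(dim(m), 1L)), 1.5)[, , 1]
  mx <- sm(x); my <- sm(y)
  sxx <- sm(x * x) - mx * mx
  syy <- sm(y * y) - my * my
  sxy <- sm(x * y) - mx * my
  l <- (2 * mx * my + C1) / (mx^2 + my^2 + C1)
  cs <- (2 * sxy + C2) / (sxx + syy + C2)
  list(ssim = mean(l * cs), cs = mean(cs))
}

downsample2x <- function(m) {
  d <- dim(m) %/% 2L * 2L
  m <- m[seq_len(d[1]), seq_len(d[2]), drop = FALSE]
  0.25 * (m[seq(1, d[1], 2), seq(1, d[2], 2), drop = FALSE] +
          m[seq(2, d[1], 2), seq(1, d[2], 2), drop = FALSE] +
          m[seq(1, d[1], 2), seq(2, d[2], 2), drop = FALSE] +
          m[seq(2, d[1], 2), seq(2, d[2], 2), drop = FALSE])
}

#' Multi-scale SSIM of two 2D slices
#'
#' Standard MS-SSIM with the canonical five-scale weights (0.0448, 0.2856,
#' 0.3001, 0.2363, 0.1333); the number of scales is limited by the slice
#' size (each scale needs >= 11 px after downsampling, the SSIM window
#' width) and the weights of the used scales are renormalized. Negative
#' contrast-structure means are clamped at 0 so the result stays in [0, 1].
#'
#' @param x,y 2D matrices on a common intensity range.
#' @param dataRange intensity range (2 for normalized slices).
#' @return MS-SSIM value in [0, 1].
#' @export
msSsim2d <- function(x, y, dataRange = 2) {
  stopifnot(identical(dim(x), dim(y)))
  wAll <- c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333)
  minSide <- min(dim(x))
  nScales <- min(5L, floor(log2(minSide / 11)) + 1L)
  if (nScales < 1L)
    stop("slices too small for the SSIM scale pyramid: minimum side is 11",
         call. = FALSE)
  w <- wAll[seq_len(nScales)] / sum(wAll[seq_len(nScales)])
  val <- 1
  for (s in seq_len(nScales)) {
    comp <- ssimComponents2d(x, y, dataRange)
    if (s < nScales) {
      val <- val * max(comp$cs, 0)^w[s]
      x <- downsample2x(x); y <- downsample2x(y)
    } else {
      val <- val * max(comp$ssim, 0)^w[s]
    }
  }
  min(max(val, 0), 1)
}

#' Pairwise MS-SSIM diversity of a generated set
#'
#' Mean MS-SSIM over randomly sampled distinct pairs, computed on the
#' center slices of the three anatomical planes and averaged. Lower values
#' mean more diverse output; identical volumes give 1.
#'
#' @param set a [PatchSet-class] or list of cubes (>= 2).
#' @param nPairs number of sampled pairs.
#' @param seed seed for pair sampling.
#' @return mean MS-SSIM in [0, 1].
#' @export
msSsimDiversity <- function(set, nPairs = 50L, seed = 1L) {
  if (is(set, "PatchSet")) set <- patches(set)
  n <- length(set)
  if (n < 2L) stop("need >= 2 volumes", call. = FALSE)
  withSeed(seed, {
    nAvail <- n * (n - 1) / 2
    nPairs <- min(nPairs, nAvail)
    pairIds <- sample.int(nAvail, nPairs)
    # map linear pair id to (i, j), i < j
    vals <- vapply(pairIds, function(pid) {
      i <- 1L
      while (pid > n - i) { pid <- pid - (n - i); i <- i + 1L }
      j <- i + pid
      mean(vapply(c("sagittal", "axial", "coronal"), function(pl)
        msSsim2d(centerSlice(set[[i]], pl), centerSlice(set[[j]], pl)),
        0))
    }, 0)
    mean(vals)
  })
}

#' Single-scale 3D SSIM (volumetric variant)
#'
#' A volumetric single-scale SSIM with a 3D Gaussian window; provided as a
#' clearly separate alternative to the slice-based [msSsim2d()] (standard
#' MS-SSIM is defined on 2D images).
#'
#' @param x,y 3D arrays on a common intensity range.
#' @param dataRange intensity range.
#' @return mean SSIM in [-1, 1].
#' @export
ssim3d <- function(x, y, dataRange = 2) {
  stopifnot(identical(dim(x), dim(y)))
  C1 <- (0.01 * dataRange)^2
  C2 <- (0.03 * dataRange)^2
  sm <- function(m) gaussianSmooth3d(m, 1.5)
  mx <- sm(x); my <- sm(y)
  sxx <- sm(x * x) - mx * mx
  syy <- sm(y * y) - my * my
  sxy <- sm(x * y) - mx * my
  mean(((2 * mx * my + C1) * (2 * sxy + C2)) /
         ((mx^2 + my^2 + C1) * (sxx + syy + C2)))
}

#' Full metric report for a real/synthetic pair of sets
#'
#' Computes slice-wise FID and PSNR on the three planes, F3D, MMD^2 on
#' extractor features, and MS-SSIM diversity of the synthetic set.
#'
#' @param real,synth [PatchSet-class] objects (>= 2 each, equal sizes for
#'   PSNR).
#' @param extractor a 3D [buildFeatureExtractor()].
#' @param backend2d a 2D [buildFeatureExtractor()] for slice FID.
#' @param seed seed for PSNR pairing and MS-SSIM pair sampling.
#' @return a list (`MetricReport`) of named metric values plus batch sizes
#'   and the extractor seed.
#' @export
metricReport <- function(real, synth,
                         extractor = buildFeatureExtractor(),
                         backend2d = buildFeatureExtractor(dims = 2L),
                         seed = 1L) {
  planes <- c("sagittal", "axial", "coronal")
  fid <- vapply(planes, function(p) sliceFid(real, synth, p, backend2d), 0)
  psnr <- vapply(planes, function(p)
    slicePsnr(real, synth, p, "random", seed = seed), 0)
  fr <- extractFeatures(extractor, real)
  fs <- extractFeatures(extractor, synth)
  rep <- list(
    sliceFid = fid, slicePsnr = psnr,
    f3d = frechetDistance(featureStats(fr), featureStats(fs)),
    mmd2 = mmd2(fr, fs),
    msSsim = msSsimDiversity(synth, seed = seed),
    nReal = length(real), nSynth = length(synth),
    extractorSeed = extractor$seed, backend = "seeded-untrained-cnn2d")
  class(rep) <- "MetricReport"
  rep
}
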