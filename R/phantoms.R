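# ------------------------------------------------------------------------
# Seeded procedural phantoms: HU-valued volumes with an ellipsoidal tumor
# embedded in a pancreas-like textured region, plus optional metal-artifact
# voxels. These stand in for clinical scans so every downstream stage is
# testable without patient data.
# ------------------------------------------------------------------------

#' Phantom generator configuration
#'
#' The texture model is a correlated Gaussian field (white noise smoothed
#' with a Gaussian kernel of width `textureCorrelationLength`, then rescaled
#' back to the requested standard deviation). The tumor is a random-axis
#' ellipsoid with smooth boundary perturbation, hypodense against pancreas
#' tissue for a negative `tumorHuOffset`. Metal artifacts are voxels above
#' 200 HU placed uniformly at random inside the pancreas region.
#'
#' @param sideLength voxels per axis (>= 8).
#' @param spacingMm voxel size in mm (scalar or length 3).
#' @param tumorRadiusRange min/max tumor semi-axis in voxels; must fit in
#'   the volume with a 2-voxel margin.
#' @param backgroundHuMean,backgroundHuSd abdominal background field HU.
#' @param pancreasHuOffset pancreas tissue HU offset above background.
#' @param tumorHuOffset tumor HU offset relative to pancreas tissue
#'   (negative = hypodense).
#' @param textureCorrelationLength Gaussian smoothing width in voxels.
#' @param boundaryPerturbation relative amplitude of the tumor boundary
#'   perturbation (0 = exact ellipsoid).
#' @param nArtifactVoxels number of metal-artifact voxels (> 200 HU).
#' @param huRange clip range for tissue values; artifacts occupy
#'   `(200, huRange[2]]`. Must cover the abdominal CT range.
#' @param seed integer; fully determines the output.
#' @return A validated list of class `PhantomConfig`.
#' @export
phantomConfig <- function(sideLength = 64L, spacingMm = 1,
                          tumorRadiusRange = c(5, 9),
                          backgroundHuMean = 40, backgroundHuSd = 25,
                          pancreasHuOffset = 30, tumorHuOffset = -40,
                          textureCorrelationLength = 3,
                          boundaryPerturbation = 0.15,
                          nArtifactVoxels = 0L,
                          huRange = c(-408, 1298), seed = 1L) {
  sideLength <- as.integer(sideLength)
  if (sideLength < 8L) stop("sideLength must be >= 8", call. = FALSE)
  huPars <- c(backgroundHuMean, backgroundHuSd, pancreasHuOffset,
              tumorHuOffset, huRange)
  if (any(!is.finite(huPars))) stop("HU parameters must be finite", call. = FALSE)
  if (length(tumorRadiusRange) != 2L || any(tumorRadiusRange <= 0) ||
      tumorRadiusRange[1] > tumorRadiusRange[2])
    stop("tumorRadiusRange must be an increasing positive pair", call. = FALSE)
  if (max(tumorRadiusRange) + 2 > sideLength / 2)
    stop("tumor cannot fit inside the volume with a 2-voxel margin",
         call. = FALSE)
  if (huRange[1] > -408 || huRange[2] < 1298)
    stop("huRange must cover the abdominal CT range [-408, 1298]",
         call. = FALSE)
  structure(list(sideLength = sideLength,
                 spacingMm = as.numeric(rep(spacingMm, length.out = 3L)),
                 tumorRadiusRange = as.numeric(tumorRadiusRange),
                 backgroundHuMean = backgroundHuMean,
                 backgroundHuSd = backgroundHuSd,
                 pancreasHuOffset = pancreasHuOffset,
                 tumorHuOffset = tumorHuOffset,
                 textureCorrelationLength = textureCorrelationLength,
                 boundaryPerturbation = boundaryPerturbation,
                 nArtifactVoxels = as.integer(nArtifactVoxels),
                 huRange = as.numeric(huRange),
                 seed = as.integer(seed)),
            class = "PhantomConfig")
}

# correlated Gaussian field with the requested mean/sd
correlatedField <- function(side, mean, sd, corrLen) {
  f <- array(rnorm(side^3), rep(side, 3L))
  f <- gaussianSmooth3d(f, corrLen)
  s <- stats::sd(f)
  if (s > 0) f <- f / s
  mean + sd * f
}

#' Generate one phantom CT scan with tumor and pancreas masks
#'
#' Produces a raw-HU volume: smooth textured abdominal background, a
#' pancreas-like textured region, and one ellipsoidal tumor (offset by
#' `tumorHuOffset`) strictly inside the pancreas region. Exactly
#' `nArtifactVoxels` voxels exceed 200 HU. Deterministic given the config
#' seed.
#'
#' @param config a [phantomConfig()].
#' @return list with `volume` ([CTVolume-class]), `tumorMask` and
#'   `pancreasMask` ([MaskVolume-class], tumor a single 6-connected
#'   component contained in the pancreas mask).
#' @export
makePhantomScan <- function(config = phantomConfig()) {
  stopifnot(inherits(config, "PhantomConfig"))
  withSeed(config$seed, {
    s <- config$sideLength
    ctr <- (s + 1) / 2
    # background field
    v <- correlatedField(s, config$backgroundHuMean, config$backgroundHuSd,
                         config$textureCorrelationLength)
    ax <- seq_len(s)
    g <- expand.grid(i = ax, j = ax, k = ax)
    # tumor: random-semi-axis ellipsoid with smooth boundary perturbation
    rr <- config$tumorRadiusRange
    semi <- runif(3, rr[1], rr[2])
    lev <- array(sqrt((g$i - ctr)^2 / semi[1]^2 +
                      (g$j - ctr)^2 / semi[2]^2 +
                      (g$k - ctr)^2 / semi[3]^2), rep(s, 3L))
    if (config$boundaryPerturbation > 0) {
      pert <- correlatedField(s, 0, config$boundaryPerturbation,
                              max(2, config$textureCorrelationLength))
      lev <- lev + pert
    }
    tumor <- largestComponent6(lev <= 1)
    if (!any(tumor)) tumor[ctr, ctr, ctr] <- TRUE   # degenerate perturbation
    # pancreas: larger ellipsoid enclosing the tumor
    pr <- pmin(semi * 2 + 3, s / 2 - 1)
    plev <- array(sqrt((g$i - ctr)^2 / pr[1]^2 +
                       (g$j - ctr)^2 / pr[2]^2 +
                       (g$k - ctr)^2 / pr[3]^2), rep(s, 3L))
    pancreas <- (plev <= 1) | dilate6(tumor)
    v[pancreas] <- v[pancreas] + config$pancreasHuOffset
    v[tumor] <- v[tumor] + config$tumorHuOffset
    # tissue values stay at or below the artifact threshold
    v[v > 200] <- 200
    v[v < config$huRange[1]] <- config$huRange[1]
    if (config$nArtifactVoxels > 0) {
      inside <- which(pancreas)
      if (config$nArtifactVoxels > length(inside))
        stop("more artifact voxels requested than pancreas voxels",
             call. = FALSE)
      pick <- sample(inside, config$nArtifactVoxels)
      v[pick] <- runif(config$nArtifactVoxels, 800, config$huRange[2])
    }
    list(volume = CTVolume(v, spacing = config$spacingMm,
                           intensityDomain = "raw_hu"),
         tumorMask = MaskVolume(tumor, label = "tumor"),
         pancreasMask = MaskVolume(pancreas, label = "pancreas"))
  })
}

#' Generate a pancreas-like texture cube
#'
#' A cube fully filled with correlated Gaussian texture at pancreas-tissue
#' intensity; no empty border. Deterministic given the config seed.
#'
#' @param config a [phantomConfig()].
#' @return A raw-HU [CTVolume-class] of side `sideLength`.
#' @export
makeTextureCube <- function(config = phantomConfig()) {
  stopifnot(inherits(config, "PhantomConfig"))
  withSeed(config$seed, {
    v <- correlatedField(config$sideLength,
                         config$backgroundHuMean + config$pancreasHuOffset,
                         config$backgroundHuSd,
                         config$textureCorrelationLength)
    v[v > 200] <- 200
    v[v < config$huRange[1]] <- config$huRange[1]
    CTVolume(v, spacing = config$spacingMm, intensityDomain = "raw_hu")
  })
}

#' Generate a labeled phantom cohort for the classifier
#'
#' `nTumor` volumes containing a tumor region plus `nHealthy` plain texture
#' cubes, window-normalized, labeled, and tagged `provenance =
#' "real-phantom"`. Per-item seeds are derived from the config seed so the
#' cohort is reproducible item by item.
#'
#' @param nTumor,nHealthy item counts (>= 0).
#' @param config a [phantomConfig()]; `sideLength` sets the cube side.
#' @param preprocess a [preprocessConfig()] used for window normalization.
#' @return A [ClassifierDataset-class] with `nTumor + nHealthy` items.
#' @export
makeLabeledCohort <- function(nTumor, nHealthy, config = phantomConfig(),
                              preprocess = preprocessConfig()) {
  stopifnot(inherits(config, "PhantomConfig"), nTumor >= 0, nHealthy >= 0)
  vols <- vector("list", nTumor + nHealthy)
  labels <- character(nTumor + nHealthy)
  for (i in seq_len(nTumor)) {
    cfg <- config
    cfg$seed <- deriveSeed(config$seed, i)
    scan <- makePhantomScan(cfg)
    vols[[i]] <- voxels(normalizeWindow(scan$volume, preprocess))
    labels[i] <- "tumor"
  }
  for (i in seq_len(nHealthy)) {
    cfg <- config
    cfg$seed <- deriveSeed(config$seed, nTumor + i)
    cube <- makeTextureCube(cfg)
    vols[[nTumor + i]] <- voxels(normalizeWindow(cube, preprocess))
    labels[nTumor + i] <- "healthy"
  }
  ClassifierDataset(vols, labels, provenance = "real-phantom")
}

#' Write a phantom cohort to disk as NIfTI plus a manifest CSV
#'
#' @param dataset a [ClassifierDataset-class].
#' @param dir output directory.
#' @param spacingMm voxel spacing recorded in the headers.
#' @return manifest path, invisibly.
#' @export
writeCohort <- function(dataset, dir, spacingMm = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(dataset@volumes)
  paths <- character(n)
  for (i in seq_len(n)) {
    paths[i] <- file.path(dir, sprintf("vol-%04d.nii.gz", i))
    writeVolume(CTVolume(dataset@volumes[[i]], spacing = spacingMm,
                         intensityDomain = "normalized"), paths[i])
  }
  manifest <- data.frame(path = paths,
                         label = as.character(dataset@labels),
                         provenance = dataset@provenance)
  mpath <- file.path(dir, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}
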