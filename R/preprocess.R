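# ------------------------------------------------------------------------
# The CT preprocessing chain: isotropic resampling, soft-tissue window
# normalization, metal-artifact suppression, centroid patch extraction and
# rotation augmentation.
# ------------------------------------------------------------------------

#' Preprocessing configuration
#'
#' Holds the soft-tissue window, the metal-artifact threshold and the patch
#' geometry. Defaults follow the abdominal soft-tissue protocol: HU window
#' \eqn{[-100, 170]}, artifacts above 200 HU, 1 mm isotropic spacing, tumor
#' patches 32^3 and pancreas patches 64^3.
#'
#' @param windowLo,windowHi HU window bounds (lo < hi).
#' @param artifactThreshold HU above which a voxel counts as metal artifact;
#'   must exceed `windowHi`.
#' @param targetSpacing target isotropic voxel size in mm.
#' @param tumorSide,pancreasSide patch sides in voxels (powers of two >= 8).
#' @return A validated list of class `PreprocessConfig`.
#' @export
preprocessConfig <- function(windowLo = -100, windowHi = 170,
                             artifactThreshold = 200, targetSpacing = 1,
                             tumorSide = 32L, pancreasSide = 64L) {
  isPow2 <- function(n) n >= 8 && bitwAnd(as.integer(n), as.integer(n) - 1L) == 0L
  if (!windowLo < windowHi) stop("windowLo must be < windowHi", call. = FALSE)
  if (!artifactThreshold > windowHi)
    stop("artifactThreshold must exceed windowHi", call. = FALSE)
  if (targetSpacing <= 0) stop("targetSpacing must be > 0", call. = FALSE)
  if (!isPow2(tumorSide) || !isPow2(pancreasSide))
    stop("patch sides must be powers of two >= 8", call. = FALSE)
  structure(list(windowLo = windowLo, windowHi = windowHi,
                 artifactThreshold = artifactThreshold,
                 targetSpacing = targetSpacing,
                 tumorSide = as.integer(tumorSide),
                 pancreasSide = as.integer(pancreasSide)),
            class = "PreprocessConfig")
}

#' Resample a volume to isotropic voxel spacing
#'
#' Trilinear interpolation on the voxel-center grid; the physical extent of
#' the output matches the input to within one voxel. Masks must be
#' resampled with `method = "nearest"` to stay binary.
#'
#' @param vol a [CTVolume-class].
#' @param targetSpacing target isotropic spacing in mm (default 1).
#' @param method `"trilinear"` (intensities) or `"nearest"` (labels).
#' @return A [CTVolume-class] with spacing `(t, t, t)`.
#' @export
resampleIsotropic <- function(vol, targetSpacing = 1,
                              method = c("trilinear", "nearest")) {
  stopifnot(is(vol, "CTVolume"))
  method <- match.arg(method)
  if (targetSpacing <= 0) stop("targetSpacing must be > 0", call. = FALSE)
  d <- dim(vol@voxels)
  if (any(d < 2L))
    stop("cannot resample a degenerate volume (axis with < 2 voxels)",
         call. = FALSE)
  sp <- vol@spacing
  if (all(abs(sp - targetSpacing) < 1e-12)) return(vol)
  extent <- d * sp                               # mm per axis
  outDim <- pmax(2L, as.integer(round(extent / targetSpacing)))
  # voxel-center positions: center i sits at (i - 0.5) * spacing mm
  coords <- lapply(1:3, function(ax) {
    mm <- (seq_len(outDim[ax]) - 0.5) * targetSpacing
    mm / sp[ax] + 0.5                            # fractional input index
  })
  g <- expand.grid(i = coords[[1]], j = coords[[2]], k = coords[[3]])
  # clamp to the voxel-center hull so edge samples extrapolate flat
  ci <- pmin(pmax(g$i, 1), d[1])
  cj <- pmin(pmax(g$j, 1), d[2])
  ck <- pmin(pmax(g$k, 1), d[3])
  vals <- if (method == "trilinear")
    sampleTrilinear(vol@voxels, ci, cj, ck)
  else sampleNearest(vol@voxels, ci, cj, ck)
  CTVolume(array(vals, outDim), spacing = targetSpacing,
           intensityDomain = vol@intensityDomain)
}

#' Resample a mask with nearest-neighbor interpolation
#' @param mask a [MaskVolume-class].
#' @param spacing original spacing of the mask grid (mm, length 3).
#' @param targetSpacing target isotropic spacing in mm.
#' @return A [MaskVolume-class].
#' @export
resampleMask <- function(mask, spacing, targetSpacing = 1) {
  vol <- CTVolume(mask@voxels, spacing = spacing, intensityDomain = "raw_hu")
  out <- resampleIsotropic(vol, targetSpacing, method = "nearest")
  MaskVolume(out@voxels != 0, label = mask@label)
}

#' Normalize a raw-HU volume onto [-1, 1] through the soft-tissue window
#'
#' Values are clipped to `[windowLo, windowHi]` and affinely mapped onto
#' \eqn{[-1, 1]}; the result carries `intensityDomain = "normalized"`.
#' The window endpoints map to -1 and +1 and the window midpoint to 0.
#'
#' @param vol a raw-HU [CTVolume-class].
#' @param config a [preprocessConfig()].
#' @return A normalized [CTVolume-class].
#' @export
normalizeWindow <- function(vol, config = preprocessConfig()) {
  stopifnot(is(vol, "CTVolume"))
  if (!identical(vol@intensityDomain, "raw_hu"))
    stop("normalizeWindow expects a raw-HU volume (already normalized?)",
         call. = FALSE)
  v <- vol@voxels
  v[v < config$windowLo] <- config$windowLo
  v[v > config$windowHi] <- config$windowHi
  v <- 2 * (v - config$windowLo) / (config$windowHi - config$windowLo) - 1
  CTVolume(v, spacing = vol@spacing, intensityDomain = "normalized")
}

#' Replace metal-artifact voxels with the mean pancreas HU
#'
#' Every voxel strictly above `artifactThreshold` is replaced by the mean HU
#' over the pancreas mask, computed before any replacement; all other voxels
#' are untouched.
#'
#' @param vol a raw-HU [CTVolume-class].
#' @param pancreasMask a non-empty [MaskVolume-class] aligned to `vol`.
#' @param config a [preprocessConfig()].
#' @return A raw-HU [CTVolume-class] with artifacts suppressed.
#' @export
suppressMetal <- function(vol, pancreasMask, config = preprocessConfig()) {
  stopifnot(is(vol, "CTVolume"), is(pancreasMask, "MaskVolume"))
  if (!identical(vol@intensityDomain, "raw_hu"))
    stop("suppressMetal operates on raw HU values", call. = FALSE)
  if (!identical(dim(vol@voxels), dim(pancreasMask@voxels)))
    stop("mask shape does not match volume", call. = FALSE)
  if (sum(pancreasMask@voxels) == 0)
    stop("empty pancreas mask: replacement value undefined", call. = FALSE)
  v <- vol@voxels
  replacement <- mean(v[pancreasMask@voxels != 0])
  v[v > config$artifactThreshold] <- replacement
  CTVolume(v, spacing = vol@spacing, intensityDomain = "raw_hu")
}

#' Crop a fixed-side cube centered on a mask centroid
#'
#' The cube is centered on the mask centroid (rounded to the nearest voxel).
#' If the cube overruns the volume, the volume is padded with the window
#' minimum (-1 in the normalized domain) before cropping. Crops are
#' half-open: a centroid at voxel c spans `[c - side/2, c + side/2)`.
#'
#' @param vol a normalized [CTVolume-class].
#' @param mask a non-empty [MaskVolume-class]; use the tumor mask for tumor
#'   patches and the pancreas mask for pancreas cubes.
#' @param side cube side in voxels.
#' @param fill pad value (default -1, the window minimum).
#' @return A [PatchSet-class] cube (plain 3D array) with attributes
#'   `tissueClass` and `sourceId`; see [PatchSet()] for collecting them.
#' @export
cropPatch <- function(vol, mask, side, fill = -1) {
  stopifnot(is(vol, "CTVolume"), is(mask, "MaskVolume"))
  if (!identical(vol@intensityDomain, "normalized"))
    stop("cropPatch expects a normalized volume", call. = FALSE)
  if (sum(mask@voxels) == 0) stop("empty mask", call. = FALSE)
  side <- as.integer(side)
  d <- dim(vol@voxels)
  w <- which(mask@voxels != 0, arr.ind = TRUE)
  centroid <- round(colMeans(w))
  lo <- centroid - side %/% 2L                   # half-open [lo, lo + side)
  hi <- lo + side - 1L
  padLo <- pmax(0L, 1L - lo)
  padHi <- pmax(0L, hi - d)
  v <- padArray3d(vol@voxels, cbind(padLo, padHi), value = fill)
  lo <- lo + padLo
  cube <- v[lo[1]:(lo[1] + side - 1L),
            lo[2]:(lo[2] + side - 1L),
            lo[3]:(lo[3] + side - 1L)]
  attr(cube, "tissueClass") <- mask@label
  cube
}

#' Rotation augmentation of a patch
#'
#' One rotated copy per (axis, angle) pair, rotated about the cube center
#' with trilinear interpolation; voxels rotated in from outside the field
#' are filled with -1. Default angles are the training increments 12, 24,
#' 36, 48 and 72 degrees on all three axes, i.e. 15 copies per input.
#'
#' @param patch a normalized cube (3D array).
#' @param angles rotation angles in degrees.
#' @param axes axes to rotate about (subset of 1:3).
#' @param tissueClass tissue label for the returned set.
#' @return A [PatchSet-class] with `length(angles) * length(axes)` patches.
#' @export
augmentRotations <- function(patch, angles = c(12, 24, 36, 48, 72),
                             axes = 1:3, tissueClass = NULL) {
  stopifnot3d(patch, "patch")
  if (is.null(tissueClass))
    tissueClass <- attr(patch, "tissueClass") %||% "tumor"
  out <- vector("list", length(angles) * length(axes))
  ids <- character(length(out))
  i <- 0L
  for (ax in axes) for (ang in angles) {
    i <- i + 1L
    r <- rotateCube(patch, ax, ang, fill = -1)
    r[r < -1] <- -1; r[r > 1] <- 1              # interpolation can overshoot
    out[[i]] <- array(r, dim(r))                # plain cube, no attributes
    ids[i] <- sprintf("rot-ax%d-%gdeg", ax, ang)
  }
  PatchSet(out, tissueClass = tissueClass, provenance = "augmented",
           sourceIds = ids)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Full preprocessing chain for one scan
#'
#' resample (trilinear / nearest for masks) -> metal suppression -> window
#' normalization -> centroid crop, returning the tumor and pancreas patches
#' for one scan. Deterministic: identical inputs give identical patches.
#'
#' @param vol raw-HU [CTVolume-class].
#' @param tumorMask,pancreasMask aligned [MaskVolume-class] objects.
#' @param config a [preprocessConfig()].
#' @return list with elements `tumor` (side `tumorSide` cube) and
#'   `pancreas` (side `pancreasSide` cube).
#' @export
preprocessScan <- function(vol, tumorMask, pancreasMask,
                           config = preprocessConfig()) {
  sp <- vol@spacing
  v <- resampleIsotropic(vol, config$targetSpacing)
  tm <- resampleMask(tumorMask, sp, config$targetSpacing)
  pm <- resampleMask(pancreasMask, sp, config$targetSpacing)
  v <- suppressMetal(v, pm, config)
  v <- normalizeWindow(v, config)
  list(tumor = cropPatch(v, tm, config$tumorSide),
       pancreas = cropPatch(v, pm, config$pancreasSide))
}
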