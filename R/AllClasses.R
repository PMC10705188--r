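#' CTVolume: a 3D scalar grid with voxel spacing and intensity domain
#'
#' The basic volumetric container of the package. Voxel values are either
#' raw Hounsfield units (\code{intensityDomain = "raw_hu"}) or soft-tissue
#' window-normalized intensities in \eqn{[-1, 1]}
#' (\code{intensityDomain = "normalized"}).
#'
#' @slot voxels 3D numeric array.
#' @slot spacing numeric length-3, voxel size in mm per axis (all > 0).
#' @slot intensityDomain one of \code{"raw_hu"}, \code{"normalized"}.
#'
#' @seealso [CTVolume()], [normalizeWindow()], [resampleIsotropic()]
#' @export
setClass("CTVolume",
         representation(voxels = "array", spacing = "numeric",
                        intensityDomain = "character"),
         prototype(spacing = c(1, 1, 1), intensityDomain = "raw_hu"))

setValidity("CTVolume", function(object) {
  msg <- character()
  if (length(dim(object@voxels)) != 3L)
    msg <- c(msg, "voxels must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive finite values (mm)")
  if (!object@intensityDomain %in% c("raw_hu", "normalized"))
    msg <- c(msg, "intensityDomain must be 'raw_hu' or 'normalized'")
  if (any(!is.finite(object@voxels)))
    msg <- c(msg, "voxel values must all be finite")
  if (identical(object@intensityDomain, "normalized") &&
      length(object@voxels) &&
      (min(object@voxels) < -1 - 1e-9 || max(object@voxels) > 1 + 1e-9))
    msg <- c(msg, "normalized volumes must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a CTVolume
#'
#' @param voxels 3D numeric array.
#' @param spacing voxel spacing in mm (length 3, recycled from length 1).
#' @param intensityDomain `"raw_hu"` (default) or `"normalized"`.
#' @return A [CTVolume-class] object.
#' @examples
#' vol <- CTVolume(array(0, c(8, 8, 8)), spacing = 1)
#' @export
CTVolume <- function(voxels, spacing = c(1, 1, 1),
                     intensityDomain = "raw_hu") {
  new("CTVolume", voxels = voxels,
      spacing = as.numeric(rep(spacing, length.out = 3L)),
      intensityDomain = intensityDomain)
}

#' MaskVolume: a binary segmentation mask aligned to a CTVolume
#'
#' @slot voxels 3D array with values in \{0, 1\}.
#' @slot label `"tumor"` or `"pancreas"`.
#' @export
setClass("MaskVolume",
         representation(voxels = "array", label = "character"),
         prototype(label = "tumor"))

setValidity("MaskVolume", function(object) {
  msg <- character()
  if (length(dim(object@voxels)) != 3L)
    msg <- c(msg, "mask voxels must be a 3D array")
  if (!all(object@voxels %in% c(0, 1)))
    msg <- c(msg, "mask values must be 0/1")
  if (!object@label %in% c("tumor", "pancreas"))
    msg <- c(msg, "label must be 'tumor' or 'pancreas'")
  if (length(msg)) msg else TRUE
})

#' Construct a MaskVolume
#' @param voxels 3D array (logical or 0/1 numeric).
#' @param label `"tumor"` or `"pancreas"`.
#' @return A [MaskVolume-class] object.
#' @export
MaskVolume <- function(voxels, label = "tumor") {
  new("MaskVolume", voxels = array(as.numeric(voxels != 0), dim(voxels)),
      label = label)
}

#' PatchSet: an ordered collection of same-side normalized cubes
#'
#' The training / synthesis currency of the GAN: tumor patches are 32^3 and
#' pancreas patches 64^3 at paper scale (any power-of-two side is accepted).
#'
#' @slot patches list of 3D arrays, all of dimension side^3.
#' @slot side integer cube side.
#' @slot tissueClass `"tumor"` or `"pancreas"`.
#' @slot provenance character scalar, e.g. `"real-phantom"` or `"synthetic"`.
#' @slot sourceIds character vector of per-patch identifiers.
#' @export
setClass("PatchSet",
         representation(patches = "list", side = "integer",
                        tissueClass = "character", provenance = "character",
                        sourceIds = "character"))

setValidity("PatchSet", function(object) {
  msg <- character()
  if (length(object@patches)) {
    ok <- vapply(object@patches, function(p)
      is.array(p) && identical(dim(p), rep(object@side, 3L)), TRUE)
    if (!all(ok)) msg <- c(msg, "all patches must be cubes of the stated side")
    rng <- range(vapply(object@patches, range, numeric(2)))
    if (!all(is.finite(rng))) msg <- c(msg, "patch values must be finite")
    if (rng[1] < -1 - 1e-9 || rng[2] > 1 + 1e-9)
      msg <- c(msg, "patch values must lie in [-1, 1] (normalized domain)")
  }
  if (!object@tissueClass %in% c("tumor", "pancreas"))
    msg <- c(msg, "tissueClass must be 'tumor' or 'pancreas'")
  if (length(object@sourceIds) != length(object@patches))
    msg <- c(msg, "sourceIds must have one entry per patch")
  if (length(msg)) msg else TRUE
})

#' Construct a PatchSet
#' @param patches list of same-side normalized cubes.
#' @param tissueClass `"tumor"` or `"pancreas"`.
#' @param provenance free-text provenance tag.
#' @param sourceIds per-patch identifiers (defaults to running numbers).
#' @return A [PatchSet-class] object.
#' @export
PatchSet <- function(patches, tissueClass = "tumor",
                     provenance = "unknown", sourceIds = NULL) {
  side <- if (length(patches)) dim(patches[[1]])[1] else 0L
  if (is.null(sourceIds))
    sourceIds <- sprintf("%s-%04d", tissueClass, seq_along(patches))
  new("PatchSet", patches = patches, side = as.integer(side),
      tissueClass = tissueClass, provenance = provenance,
      sourceIds = as.character(sourceIds))
}

#' FeatureStats: Gaussian summary of an extracted feature distribution
#'
#' Feature-wise mean vector and covariance matrix of a batch of feature
#' vectors; the operands of the Frechet distance.
#'
#' @slot mu numeric mean vector.
#' @slot sigma covariance matrix.
#' @slot n sample count (>= 2).
#' @export
setClass("FeatureStats",
         representation(mu = "numeric", sigma = "matrix", n = "integer"))

setValidity("FeatureStats", function(object) {
  msg <- character()
  if (nrow(object@sigma) != length(object@mu) ||
      ncol(object@sigma) != length(object@mu))
    msg <- c(msg, "C must be square and match mu length")
  if (max(abs(object@sigma - t(object@sigma))) > 1e-8 * (1 + max(abs(object@sigma))))
    msg <- c(msg, "C must be symmetric")
  if (object@n < 2L) msg <- c(msg, "n must be >= 2")
  if (length(msg)) msg else TRUE
})

#' TrainLog: per-epoch GAN loss history with checkpoint registry
#'
#' @slot epochs integer epochs logged.
#' @slot gLoss generator loss per epoch.
#' @slot dLoss discriminator objective per epoch.
#' @slot checkpoints named list (epoch as name) of checkpoint objects.
#' @slot config the GANConfig used.
#' @slot seed integer seed of the run.
#' @export
setClass("TrainLog",
         representation(epochs = "integer", gLoss = "numeric",
                        dLoss = "numeric", checkpoints = "list",
                        config = "list", seed = "integer"))

setValidity("TrainLog", function(object) {
  msg <- character()
  if (length(object@gLoss) != length(object@epochs) ||
      length(object@dLoss) != length(object@epochs))
    msg <- c(msg, "loss vectors must match epochs")
  if (length(object@gLoss) && any(!is.finite(object@gLoss)))
    msg <- c(msg, "generator losses must be finite")
  if (length(object@dLoss) && any(!is.finite(object@dLoss)))
    msg <- c(msg, "discriminator losses must be finite")
  if (length(msg)) msg else TRUE
})

#' ClassifierDataset: labeled volumes with provenance
#'
#' @slot volumes list of same-side 3D arrays in normalized intensity.
#' @slot labels factor with levels `healthy`, `tumor`.
#' @slot provenance character per item (`"real-phantom"`, `"synthetic"`, ...).
#' @slot side integer cube side.
#' @export
setClass("ClassifierDataset",
         representation(volumes = "list", labels = "factor",
                        provenance = "character", side = "integer"))

setValidity("ClassifierDataset", function(object) {
  msg <- character()
  n <- length(object@volumes)
  if (length(object@labels) != n || length(object@provenance) != n)
    msg <- c(msg, "labels and provenance must have one entry per volume")
  if (!identical(levels(object@labels), c("healthy", "tumor")))
    msg <- c(msg, "labels must be a factor with levels healthy, tumor")
  if (n) {
    ok <- vapply(object@volumes, function(v)
      identical(dim(v), rep(object@side, 3L)), TRUE)
    if (!all(ok)) msg <- c(msg, "all volumes must be cubes of the stated side")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ClassifierDataset
#' @param volumes list of same-side cubes.
#' @param labels character/factor of `"healthy"`/`"tumor"` per volume.
#' @param provenance character per volume; recycled from length 1.
#' @return A [ClassifierDataset-class] object.
#' @export
ClassifierDataset <- function(volumes, labels,
                              provenance = "real-phantom") {
  side <- if (length(volumes)) dim(volumes[[1]])[1] else 0L
  new("ClassifierDataset", volumes = volumes,
      labels = factor(as.character(labels), levels = c("healthy", "tumor")),
      provenance = rep(provenance, length.out = length(volumes)),
      side = as.integer(side))
}

#' EvalCurves: ROC / PR curves with AUCs and a confusion matrix
#'
#' @slot roc data.frame with columns `threshold`, `fpr`, `tpr`.
#' @slot pr data.frame with columns `threshold`, `recall`, `precision`.
#' @slot rocAuc area under the ROC curve (trapezoid).
#' @slot prAuc area under the PR curve (trapezoid).
#' @slot confusion named numeric: TP, FP, TN, FN at threshold 0.5.
#' @export
setClass("EvalCurves",
         representation(roc = "data.frame", pr = "data.frame",
                        rocAuc = "numeric", prAuc = "numeric",
                        confusion = "numeric"))

setValidity("EvalCurves", function(object) {
  msg <- character()
  if (object@rocAuc < -1e-9 || object@rocAuc > 1 + 1e-9)
    msg <- c(msg, "rocAuc must lie in [0, 1]")
  if (object@prAuc < -1e-9 || object@prAuc > 1 + 1e-9)
    msg <- c(msg, "prAuc must lie in [0, 1]")
  if (!all(c("TP", "FP", "TN", "FN") %in% names(object@confusion)))
    msg <- c(msg, "confusion must contain TP, FP, TN, FN")
  if (length(msg)) msg else TRUE
})
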