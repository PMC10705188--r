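#' Accessors for volumetric containers
#'
#' `voxels()` returns the raw 3D array, `spacing()` the voxel size in mm,
#' `intensityDomain()` the intensity tag of a [CTVolume-class].
#'
#' @param object a CTVolume or MaskVolume.
#' @return `voxels()`: a 3D array; `spacing()`: numeric length 3;
#'   `intensityDomain()`: character scalar.
#' @name volume-accessors
NULL

#' @rdname volume-accessors
#' @export
setGeneric("voxels", function(object) standardGeneric("voxels"))
#' @rdname volume-accessors
#' @export
setGeneric("spacing", function(object) standardGeneric("spacing"))
#' @rdname volume-accessors
#' @export
setGeneric("intensityDomain",
           function(object) standardGeneric("intensityDomain"))

#' @rdname volume-accessors
#' @export
setMethod("voxels", "CTVolume", function(object) object@voxels)
#' @rdname volume-accessors
#' @export
setMethod("voxels", "MaskVolume", function(object) object@voxels)
#' @rdname volume-accessors
#' @export
setMethod("spacing", "CTVolume", function(object) object@spacing)
#' @rdname volume-accessors
#' @export
setMethod("intensityDomain", "CTVolume",
          function(object) object@intensityDomain)

#' Mask label accessor
#' @param object a [MaskVolume-class].
#' @return character scalar, `"tumor"` or `"pancreas"`.
#' @export
setGeneric("maskLabel", function(object) standardGeneric("maskLabel"))
#' @rdname maskLabel
#' @export
setMethod("maskLabel", "MaskVolume", function(object) object@label)

#' PatchSet accessors
#'
#' `patches()` returns the list of cubes, `patchSide()` the cube side,
#' `tissueClass()` the tissue label, `provenance()` the provenance tag.
#'
#' @param object a [PatchSet-class] or [ClassifierDataset-class].
#' @return see description.
#' @name patchset-accessors
NULL

#' @rdname patchset-accessors
#' @export
setGeneric("patches", function(object) standardGeneric("patches"))
#' @rdname patchset-accessors
#' @export
setGeneric("patchSide", function(object) standardGeneric("patchSide"))
#' @rdname patchset-accessors
#' @export
setGeneric("tissueClass", function(object) standardGeneric("tissueClass"))
#' @rdname patchset-accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))

#' @rdname patchset-accessors
#' @export
setMethod("patches", "PatchSet", function(object) object@patches)
#' @rdname patchset-accessors
#' @export
setMethod("patchSide", "PatchSet", function(object) object@side)
#' @rdname patchset-accessors
#' @export
setMethod("tissueClass", "PatchSet", function(object) object@tissueClass)
#' @rdname patchset-accessors
#' @export
setMethod("provenance", "PatchSet", function(object) object@provenance)
#' @rdname patchset-accessors
#' @export
setMethod("provenance", "ClassifierDataset", function(object) object@provenance)

#' ClassifierDataset accessors
#' @param object a [ClassifierDataset-class].
#' @return `datasetVolumes()`: list of cubes; `datasetLabels()`: factor.
#' @name dataset-accessors
NULL

#' @rdname dataset-accessors
#' @export
setGeneric("datasetVolumes", function(object) standardGeneric("datasetVolumes"))
#' @rdname dataset-accessors
#' @export
setGeneric("datasetLabels", function(object) standardGeneric("datasetLabels"))
#' @rdname dataset-accessors
#' @export
setMethod("datasetVolumes", "ClassifierDataset", function(object) object@volumes)
#' @rdname dataset-accessors
#' @export
setMethod("datasetLabels", "ClassifierDataset", function(object) object@labels)

#' Number of items in a container
#' @param x a PatchSet or ClassifierDataset.
#' @return integer count.
#' @export
setMethod("length", "PatchSet", function(x) length(x@patches))
#' @rdname length-PatchSet-method
#' @export
setMethod("length", "ClassifierDataset", function(x) length(x@volumes))

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("CTVolume %dx%dx%d voxels, spacing %s mm, domain '%s'\n",
              d[1], d[2], d[3],
              paste(signif(object@spacing, 4), collapse = "x"),
              object@intensityDomain))
  if (length(object@voxels))
    cat(sprintf("  intensity range [%.2f, %.2f]\n",
                min(object@voxels), max(object@voxels)))
})

setMethod("show", "MaskVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("MaskVolume '%s' %dx%dx%d, %d foreground voxels\n",
              object@label, d[1], d[2], d[3], sum(object@voxels)))
})

setMethod("show", "PatchSet", function(object) {
  cat(sprintf("PatchSet of %d '%s' patches, side %d, provenance '%s'\n",
              length(object@patches), object@tissueClass, object@side,
              object@provenance))
})

setMethod("show", "FeatureStats", function(object) {
  cat(sprintf("FeatureStats: %d-dim features from n = %d samples\n",
              length(object@mu), object@n))
})

setMethod("show", "TrainLog", function(object) {
  cat(sprintf("TrainLog: %d epochs, %d checkpoints, seed %d\n",
              length(object@epochs), length(object@checkpoints),
              object@seed))
  if (length(object@gLoss))
    cat(sprintf("  final losses: G = %.4f, D = %.4f\n",
                tail(object@gLoss, 1), tail(object@dLoss, 1)))
})

setMethod("show", "ClassifierDataset", function(object) {
  tab <- table(object@labels)
  cat(sprintf(
    "ClassifierDataset: %d volumes (side %d): %d tumor / %d healthy; %d synthetic\n",
    length(object@volumes), object@side, tab[["tumor"]], tab[["healthy"]],
    sum(object@provenance == "synthetic")))
})

setMethod("show", "EvalCurves", function(object) {
  cat(sprintf("EvalCurves: ROC-AUC %.3f, PR-AUC %.3f\n",
              object@rocAuc, object@prAuc))
  cat(sprintf("  confusion @0.5: TP=%d FP=%d TN=%d FN=%d\n",
              object@confusion[["TP"]], object@confusion[["FP"]],
              object@confusion[["TN"]], object@confusion[["FN"]]))
})
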