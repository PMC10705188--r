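#' Read a 3D volume from a NIfTI file
#'
#' Reads a `.nii` / `.nii.gz` file into a [CTVolume-class], taking the voxel
#' spacing from the header. The payload must be 3-dimensional.
#'
#' @param path path to the NIfTI file.
#' @param intensityDomain intensity tag to attach; volumes written by
#'   [writeVolume()] record their domain in the NIfTI `intent_name` field
#'   and restore it automatically.
#' @return A [CTVolume-class].
#' @export
readVolume <- function(path, intensityDomain = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop("malformed NIfTI file '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D volume in '", path, "', got ", length(d),
         " dimensions", call. = FALSE)
  if (is.null(intensityDomain)) {
    hdr <- RNifti::niftiHeader(img)
    intensityDomain <- if (identical(hdr$intent_name, "normalized"))
      "normalized" else "raw_hu"
  }
  CTVolume(array(as.numeric(img), d),
           spacing = RNifti::pixdim(img),
           intensityDomain = intensityDomain)
}

#' Write a CTVolume to a NIfTI file
#'
#' Voxels are stored as 32-bit floats; spacing goes into `pixdim` and the
#' intensity domain into `intent_name`, so a write/read round trip preserves
#' values to float precision and metadata exactly.
#'
#' @param vol a [CTVolume-class].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
writeVolume <- function(vol, path) {
  stopifnot(is(vol, "CTVolume"))
  img <- RNifti::asNifti(vol@voxels)
  RNifti::pixdim(img) <- vol@spacing
  img <- RNifti::asNifti(img, list(intent_name = vol@intensityDomain))
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Read / write a binary mask as NIfTI
#'
#' @param path file path.
#' @param label mask label to attach on read.
#' @return [readMask()]: a [MaskVolume-class]; [writeMask()]: `path`.
#' @export
readMask <- function(path, label = "tumor") {
  vol <- readVolume(path, intensityDomain = "raw_hu")
  MaskVolume(vol@voxels != 0, label = label)
}

#' @rdname readMask
#' @param mask a [MaskVolume-class].
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "MaskVolume"))
  img <- RNifti::asNifti(mask@voxels)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Write a PatchSet to a directory of NIfTI files with a manifest
#'
#' @param set a [PatchSet-class].
#' @param dir output directory (created if missing).
#' @return path of the manifest CSV, invisibly.
#' @export
writePatchSet <- function(set, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(set@patches))
  for (i in seq_along(set@patches)) {
    paths[i] <- file.path(dir, paste0(set@sourceIds[i], ".nii.gz"))
    writeVolume(CTVolume(set@patches[[i]], spacing = 1,
                         intensityDomain = "normalized"), paths[i])
  }
  manifest <- data.frame(path = paths, tissue_class = set@tissueClass,
                         provenance = set@provenance,
                         source_id = set@sourceIds)
  mpath <- file.path(dir, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Read a PatchSet from a manifest written by [writePatchSet()]
#'
#' @param dir directory containing `manifest.csv`.
#' @return A [PatchSet-class].
#' @export
readPatchSet <- function(dir) {
  mpath <- file.path(dir, "manifest.csv")
  if (!file.exists(mpath)) stop("no manifest.csv in ", dir, call. = FALSE)
  manifest <- read.csv(mpath, stringsAsFactors = FALSE)
  cubes <- lapply(manifest$path, function(p) voxels(readVolume(p)))
  PatchSet(cubes, tissueClass = manifest$tissue_class[1],
           provenance = manifest$provenance[1],
           sourceIds = manifest$source_id)
}
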