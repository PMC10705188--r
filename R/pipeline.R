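# ------------------------------------------------------------------------
# Orchestration: a single run configuration drives phantom generation,
# GAN training, synthesis, blending, evaluation and classification, with
# per-stage manifests (config hash + seed + artifact paths) so any run is
# traceable and resumable.
# ------------------------------------------------------------------------

#' Build a pipeline run configuration
#'
#' A single global seed fans out to per-stage derived seeds (seed + stage
#' index) so stages are independently reproducible. The defaults describe
#' a desk-scale smoke run (16^3 volumes, small networks); raise the sides,
#' channel counts and epochs for realistic training.
#'
#' @param seed global integer seed.
#' @param outDir output root directory.
#' @param stages character vector of stages to run, in dependency order,
#'   subset of `c("phantom", "gan", "synthesize", "blend", "evaluate",
#'   "classify")`.
#' @param side cube side shared by the phantom, GAN and classifier stages
#'   (divisible by 16).
#' @param nTumor,nHealthy phantom cohort sizes.
#' @param ganEpochs,ganBase GAN epochs and base channels.
#' @param nSynth number of volumes to synthesize.
#' @param blendMethod blending method for the blend stage.
#' @param classifierEpochs,classifierChannels classifier schedule.
#' @return a validated list of class `RunConfig`.
#' @export
runConfig <- function(seed = 1L, outDir = tempfile("ctgan3d-run-"),
                      stages = c("phantom", "gan", "synthesize", "blend",
                                 "evaluate", "classify"),
                      side = 16L, nTumor = 16L, nHealthy = 16L,
                      ganEpochs = 60L, ganBase = 4L, nSynth = 8L,
                      blendMethod = "II", classifierEpochs = 6L,
                      classifierChannels = c(4L, 8L, 12L, 16L)) {
  known <- c("phantom", "gan", "synthesize", "blend", "evaluate", "classify")
  if (!all(stages %in% known))
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "),
         call. = FALSE)
  if (side %% 16L != 0L)
    stop("side must be divisible by 16", call. = FALSE)
  structure(list(seed = as.integer(seed), outDir = outDir,
                 stages = stages, side = as.integer(side),
                 nTumor = as.integer(nTumor), nHealthy = as.integer(nHealthy),
                 ganEpochs = as.integer(ganEpochs),
                 ganBase = as.integer(ganBase), nSynth = as.integer(nSynth),
                 blendMethod = blendMethod,
                 classifierEpochs = as.integer(classifierEpochs),
                 classifierChannels = as.integer(classifierChannels)),
            class = "RunConfig")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys match [runConfig()] arguments.
#' @return a `RunConfig` list.
#' @export
readRunConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(runConfig, vals)
}

writeManifest <- function(dir, stage, config, seed, outputs) {
  hashed <- unclass(config)
  hashed$outDir <- NULL                     # hash the science, not the path
  entry <- list(stage = stage, configHash = rlang::hash(hashed),
                seed = seed, outputs = outputs)
  path <- file.path(dir, paste0("manifest-", stage, ".json"))
  jsonlite::write_json(entry, path, auto_unbox = TRUE, pretty = TRUE)
  entry$path <- path
  entry
}

#' Run the pipeline
#'
#' Executes the configured stages in dependency order, writing artifacts
#' and a JSON manifest (stage, config hash, derived seed, outputs) under
#' `config$outDir`. Later stages reload the artifacts of earlier ones from
#' disk, so a run can resume from any completed stage. Fails on the first
#' stage whose upstream artifact is missing.
#'
#' @param config a [runConfig()].
#' @return named list of stage manifests, invisibly; the `evaluate` and
#'   `classify` manifests carry the `MetricReport` list and the
#'   [EvalCurves-class] under `result`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  out <- config$outDir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifests <- list()
  stageIndex <- function(s)
    match(s, c("phantom", "gan", "synthesize", "blend", "evaluate",
               "classify"))
  need <- function(path, stage)
    if (!file.exists(path))
      stop("stage '", stage, "' needs missing upstream artifact: ", path,
           call. = FALSE)
  s <- config$side
  pcfgFor <- function(seed)
    phantomConfig(sideLength = s, tumorRadiusRange = c(3, s / 4),
                  seed = seed)

  if ("phantom" %in% config$stages) {
    seed <- deriveSeed(config$seed, stageIndex("phantom"))
    cohort <- makeLabeledCohort(config$nTumor, config$nHealthy,
                                pcfgFor(seed))
    dir.create(file.path(out, "phantom"), showWarnings = FALSE)
    writeCohort(cohort, file.path(out, "phantom"))
    manifests$phantom <- writeManifest(out, "phantom", config, seed,
                                       list(dir = file.path(out, "phantom")))
  }

  if ("gan" %in% config$stages) {
    seed <- deriveSeed(config$seed, stageIndex("gan"))
    mpath <- file.path(out, "phantom", "manifest.csv")
    need(mpath, "gan")
    manifest <- read.csv(mpath, stringsAsFactors = FALSE)
    tpaths <- manifest$path[manifest$label == "tumor"]
    cubes <- lapply(tpaths, function(p) voxels(readVolume(p)))
    train <- PatchSet(cubes, tissueClass = "tumor",
                      provenance = "real-phantom")
    gcfg <- ganConfig(side = s, unetDepth = 2L,
                      baseChannels = config$ganBase,
                      learningRate = 2e-4, batchSize = min(4L, length(cubes)),
                      epochs = config$ganEpochs, checkpointInterval = 20L,
                      seed = seed)
    log <- trainGan(train, gcfg)
    best <- selectCheckpoint(log)
    ckPath <- file.path(out, "checkpoint.rds")
    saveCheckpoint(log@checkpoints[[as.character(best)]], ckPath)
    writeTrainLog(log, file.path(out, "trainlog.csv"))
    manifests$gan <- writeManifest(out, "gan", config, seed,
                                   list(checkpoint = ckPath,
                                        selectedEpoch = best,
                                        trainlog = file.path(out, "trainlog.csv")))
  }

  if ("synthesize" %in% config$stages) {
    seed <- deriveSeed(config$seed, stageIndex("synthesize"))
    ckPath <- file.path(out, "checkpoint.rds")
    need(ckPath, "synthesize")
    synth <- synthesize(ckPath, config$nSynth, seed = seed,
                        tissueClass = "tumor")
    writePatchSet(synth, file.path(out, "synth"))
    manifests$synthesize <- writeManifest(out, "synthesize", config, seed,
                                          list(dir = file.path(out, "synth")))
  }

  if ("blend" %in% config$stages) {
    seed <- deriveSeed(config$seed, stageIndex("blend"))
    need(file.path(out, "synth", "manifest.csv"), "blend")
    synth <- readPatchSet(file.path(out, "synth"))
    pcube <- makeTextureCube(
      phantomConfig(sideLength = 2L * s, tumorRadiusRange = c(3, s / 4),
                    seed = seed))
    pan <- voxels(normalizeWindow(pcube))
    req <- blendRequest(patches(synth)[[1]], pan,
                        method = config$blendMethod, iterations = 50L,
                        seed = seed)
    blended <- blendVolumes(req)
    bpath <- file.path(out, "blended.nii.gz")
    writeVolume(blended, bpath)
    exportSliceMontage(blended, file.path(out, "blended-montage.png"))
    manifests$blend <- writeManifest(out, "blend", config, seed,
                                     list(volume = bpath,
                                          montage = file.path(out, "blended-montage.png")))
  }

  if ("evaluate" %in% config$stages) {
    seed <- deriveSeed(config$seed, stageIndex("evaluate"))
    need(file.path(out, "synth", "manifest.csv"), "evaluate")
    synth <- readPatchSet(file.path(out, "synth"))
    nEval <- max(4L, length(synth))
    realCfg <- pcfgFor(deriveSeed(seed, 99L))
    real <- PatchSet(lapply(seq_len(nEval), function(i) {
      cfg <- realCfg; cfg$seed <- deriveSeed(realCfg$seed, i)
      voxels(normalizeWindow(makePhantomScan(cfg)$volume))
    }), tissueClass = "tumor", provenance = "real-phantom")
    report <- metricReport(real, synth, seed = seed)
    jsonlite::write_json(report[c("sliceFid", "slicePsnr", "f3d", "mmd2",
                                  "msSsim", "nReal", "nSynth", "backend")],
                         file.path(out, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    m <- writeManifest(out, "evaluate", config, seed,
                       list(metrics = file.path(out, "metrics.json")))
    m$result <- report
    manifests$evaluate <- m
  }

  if ("classify" %in% config$stages) {
    seed <- deriveSeed(config$seed, stageIndex("classify"))
    mpath <- file.path(out, "phantom", "manifest.csv")
    need(mpath, "classify")
    manifest <- read.csv(mpath, stringsAsFactors = FALSE)
    cohort <- ClassifierDataset(
      lapply(manifest$path, function(p) voxels(readVolume(p))),
      manifest$label, manifest$provenance)
    split <- splitHoldout(cohort, 0.2, seed = seed)
    ccfg <- classifierConfig(side = s, channels = config$classifierChannels,
                             denseWidth = 16L, dropout = 0.1,
                             batchSize = 8L, learningRate = 1e-3,
                             epochs = config$classifierEpochs, seed = seed)
    fit <- trainClassifier(split$train, ccfg, kFolds = 3L)
    curves <- evaluateClassifier(fit$model, split$test)
    jsonlite::write_json(list(rocAuc = curves@rocAuc, prAuc = curves@prAuc,
                              cvAccuracy = fit$cvAccuracy,
                              confusion = as.list(curves@confusion)),
                         file.path(out, "classifier.json"),
                         auto_unbox = TRUE, digits = NA)
    m <- writeManifest(out, "classify", config, seed,
                       list(metrics = file.path(out, "classifier.json")))
    m$result <- curves
    manifests$classify <- m
  }

  invisible(manifests)
}

#' Export an orthogonal slice montage as PNG
#'
#' Writes the three center slices (sagittal, axial, coronal) side by side
#' as an 8-bit grayscale PNG. Normalized volumes are displayed with the
#' fixed window [-1, 1] (no autoscaling), so identical volumes produce
#' byte-identical files; raw-HU volumes use the soft-tissue window
#' [-100, 170].
#'
#' @param volume a [CTVolume-class] or 3D array (assumed normalized).
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
exportSliceMontage <- function(volume, path) {
  if (is(volume, "CTVolume")) {
    win <- if (identical(intensityDomain(volume), "normalized"))
      c(-1, 1) else c(-100, 170)
    v <- voxels(volume)
  } else {
    stopifnot3d(volume)
    win <- c(-1, 1)
    v <- volume
  }
  panels <- lapply(c("sagittal", "axial", "coronal"), function(pl) {
    m <- (centerSlice(v, pl) - win[1]) / diff(win)
    m[m < 0] <- 0; m[m > 1] <- 1
    m
  })
  h <- max(vapply(panels, nrow, 1L))
  w <- max(vapply(panels, ncol, 1L))
  montage <- matrix(0, h, 3L * w + 2L)   # 1-px separators
  for (i in seq_along(panels)) {
    p <- panels[[i]]
    montage[seq_len(nrow(p)), (i - 1L) * (w + 1L) + seq_len(ncol(p))] <- p
  }
  ok <- tryCatch({ png::writePNG(montage, path); TRUE },
                 error = function(e)
                   stop("cannot write montage to '", path, "': ",
                        conditionMessage(e), call. = FALSE))
  invisible(path)
}
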