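# End-to-end pipeline: simulate -> featurize -> train -> analyze
# [-> transfer], with content-hash caching and a machine-readable report.

#' Default pipeline configuration
#'
#' All stage parameters for [runPipeline()] in one validated list. Every
#' stochastic stage derives its own seed deterministically from the single
#' run seed (an md5-based fan-out), so stages are individually
#' reproducible and a rerun with the same configuration yields an
#' identical report.
#'
#' @param outDir run directory for all artifacts.
#' @param preset synthetic generator preset (see [syntheticPreset()]);
#'   ignored when `topologyPath`/`trajectoryPath` point at real data.
#' @param nFrames frames to simulate.
#' @param seed master run seed.
#' @param topologyPath,trajectoryPath,nativePath optional real input files;
#'   when set, the simulate stage is skipped.
#' @param cutoff contact cutoff in Angstrom.
#' @param pad padded map size (`NULL` = automatic).
#' @param hyperparams overrides for [cvaeHyperparams()] as a named list.
#' @param epochs training epochs.
#' @param k number of states for [assignStates()].
#' @param perplexity,bins t-SNE perplexity and landscape bins.
#' @param tsneMaxFrames frame cap for the exact t-SNE (subsampled above).
#' @param transferSeed if non-`NULL`, generate an independent trajectory
#'   with this seed and run the transfer stage.
#' @param trajFormat trajectory file format for the simulate stage.
#' @return a configuration list of class `"foldcvaeRunConfig"`.
#' @export
defaultRunConfig <- function(outDir, preset = "fs21", nFrames = 2000,
                             seed = 7, topologyPath = NULL,
                             trajectoryPath = NULL, nativePath = NULL,
                             cutoff = 8, pad = NULL,
                             hyperparams = list(nConvLayers = 2,
                                                nFilters = 16, kernel = 3,
                                                nDense = 64, latentDim = 3),
                             epochs = 30, k = 4, perplexity = 30,
                             bins = 64, tsneMaxFrames = 2000,
                             transferSeed = NULL, trajFormat = "pdb") {
  cfg <- list(outDir = outDir, preset = preset, nFrames = nFrames,
              seed = as.integer(seed), topologyPath = topologyPath,
              trajectoryPath = trajectoryPath, nativePath = nativePath,
              cutoff = cutoff, pad = pad, hyperparams = hyperparams,
              epochs = epochs, k = k, perplexity = perplexity, bins = bins,
              tsneMaxFrames = tsneMaxFrames, transferSeed = transferSeed,
              trajFormat = trajFormat)
  validateRunConfig(cfg)
  class(cfg) <- "foldcvaeRunConfig"
  cfg
}

#' Validate a pipeline configuration
#' @param cfg a configuration list (e.g. parsed from YAML).
#' @return `cfg`, invisibly; stops with the offending keys otherwise.
#' @export
validateRunConfig <- function(cfg) {
  required <- c("outDir", "seed", "cutoff", "epochs", "k")
  missing <- setdiff(required, names(cfg))
  if (length(missing))
    stop("run configuration is missing keys: ",
         paste(missing, collapse = ", "))
  bad <- character(0)
  if (!is.numeric(cfg$seed)) bad <- c(bad, "seed")
  if (!is.numeric(cfg$cutoff) || cfg$cutoff <= 0) bad <- c(bad, "cutoff")
  if (!is.numeric(cfg$epochs) || cfg$epochs < 0) bad <- c(bad, "epochs")
  if (!is.numeric(cfg$k) || cfg$k < 1) bad <- c(bad, "k")
  if (length(bad))
    stop("invalid run configuration values for: ",
         paste(bad, collapse = ", "))
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with keys as in [defaultRunConfig()].
#' @return a configuration list of class `"foldcvaeRunConfig"`.
#' @export
readRunConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(defaultRunConfig, raw)
}

# Deterministic per-stage seed fan-out from the master seed.
stage_seed <- function(seed, stage) {
  tf <- tempfile()
  writeLines(paste(seed, stage), tf)
  h <- tools::md5sum(tf)
  unlink(tf)
  strtoi(substr(h, 1, 7), 16L)
}

log_msg <- function(stage, ...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), "[", stage, "] ", ...)
}

# Content hash of a stage: parameters plus md5 of input files.
hash_of <- function(obj, files = character(0)) {
  tf <- tempfile()
  fh <- if (length(files)) unname(tools::md5sum(files)) else character(0)
  saveRDS(list(obj, fh), tf)
  h <- unname(tools::md5sum(tf))
  unlink(tf)
  h
}

read_manifest <- function(path) {
  if (file.exists(path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else list(stages = list())
}

#' Run the full pipeline
#'
#' Executes simulate -> featurize -> train -> analyze (and optionally
#' transfer) in order, skipping stages whose configuration and inputs are
#' unchanged since the previous run (content-hash manifest). Artifacts are
#' written under `cfg$outDir`: trajectory files, `maps.rds`, `model.ckpt`,
#' `loss_trace.csv`, `embeddings.csv`, `landscape.png`, `report.json` and
#' `manifest.json`. The report contains no timestamps, so identical
#' configurations yield byte-identical reports.
#'
#' @param cfg configuration from [defaultRunConfig()] or [readRunConfig()].
#' @return invisibly, the report as a list.
#' @export
runPipeline <- function(cfg) {
  validateRunConfig(cfg)
  out <- cfg$outDir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(out, "manifest.json")
  manifest <- read_manifest(manifest_path)
  stages_run <- list()
  stage <- function(name, hash, outputs, run) {
    prev <- manifest$stages[[name]]
    if (!is.null(prev) && identical(prev, hash) &&
        all(file.exists(outputs))) {
      log_msg(name, "cached")
      stages_run[[name]] <<- "cached"
      return(invisible(FALSE))
    }
    log_msg(name, "running")
    run()
    manifest$stages[[name]] <<- hash
    stages_run[[name]] <<- "run"
    invisible(TRUE)
  }

  # -- simulate ---------------------------------------------------------
  use_real <- !is.null(cfg$trajectoryPath)
  if (use_real) {
    topo <- cfg$topologyPath
    trajfile <- cfg$trajectoryPath
    native_path <- cfg$nativePath
    labels_path <- NULL
  } else {
    sim_dir <- file.path(out, "sim")
    topo <- file.path(sim_dir, "native.pdb")
    trajfile <- file.path(sim_dir, paste0("traj.", cfg$trajFormat))
    native_path <- topo
    labels_path <- file.path(sim_dir, "labels.csv")
    sim_seed <- stage_seed(cfg$seed, "simulate")
    sim_cfg <- syntheticPreset(cfg$preset, nFrames = cfg$nFrames,
                               seed = sim_seed)
    stage("simulate", hash_of(sim_cfg), c(topo, trajfile, labels_path),
          function() {
            traj <- generateFoldingTrajectory(sim_cfg)
            writeSyntheticTrajectory(traj, sim_dir,
                                     trajFormat = cfg$trajFormat)
          })
  }

  # -- featurize --------------------------------------------------------
  maps_path <- file.path(out, "maps.rds")
  feat_par <- list(cutoff = cfg$cutoff, pad = cfg$pad)
  stage("featurize", hash_of(feat_par, c(topo, trajfile)), maps_path,
        function() {
          frames <- loadTrajectory(topo, trajfile)
          maps <- computeContactMaps(frames, cutoff = cfg$cutoff)
          maps <- padMaps(maps, if (is.null(cfg$pad))
            defaultPaddedSize(nResidues(maps)) else cfg$pad)
          writeContactMaps(maps, maps_path)
          log_msg("featurize", nFrames(maps), " frames, ",
                  mapSize(maps), "x", mapSize(maps), " maps")
        })

  # -- train ------------------------------------------------------------
  model_path <- file.path(out, "model.ckpt")
  trace_path <- file.path(out, "loss_trace.csv")
  train_seed <- stage_seed(cfg$seed, "train")
  train_par <- list(hp = cfg$hyperparams, epochs = cfg$epochs,
                    seed = train_seed)
  stage("train", hash_of(train_par, maps_path),
        c(model_path, trace_path), function() {
          maps <- readContactMaps(maps_path)
          split <- splitDataset(nFrames(maps))
          hp <- do.call(cvaeHyperparams, cfg$hyperparams)
          model <- buildModel(hp, mapSize(maps), seed = train_seed)
          model <- trainModel(model, maps, split, seed = train_seed,
                              epochs = cfg$epochs)
          tr <- lossTrace(model)
          log_msg("train", sprintf("epoch %d: train L %.3f, val L %.3f",
                                   nrow(tr), tr$train_L[nrow(tr)],
                                   tr$val_L[nrow(tr)]))
          saveModel(model, model_path)
          utils::write.csv(tr, trace_path, row.names = FALSE)
        })

  # -- analyze ----------------------------------------------------------
  report_path <- file.path(out, "report.json")
  emb_path <- file.path(out, "embeddings.csv")
  fes_path <- file.path(out, "landscape.csv")
  png_path <- file.path(out, "landscape.png")
  an_seed <- stage_seed(cfg$seed, "analyze")
  an_par <- list(k = cfg$k, perplexity = cfg$perplexity, bins = cfg$bins,
                 tsneMaxFrames = cfg$tsneMaxFrames, seed = an_seed,
                 transferSeed = cfg$transferSeed)
  stage("analyze", hash_of(an_par, c(maps_path, model_path)),
        c(report_path, emb_path), function() {
          maps <- readContactMaps(maps_path)
          model <- loadModel(model_path)
          split <- splitDataset(nFrames(maps))
          frames <- loadTrajectory(topo, trajfile)
          emb <- encodeMaps(model, maps, seed = an_seed)
          fractions <- lapply(list(train = trainIdx(split),
                                   test = testIdx(split),
                                   val = valIdx(split)), function(idx) {
            mispredictionFraction(
              reconstructionDifference(model, maps, subset = idx))
          })
          rc <- if (!is.null(native_path) && file.exists(native_path)) {
            native <- loadTrajectory(native_path)
            ref <- buildNativeReference(frameCoords(native)[1, , ])
            reactionCoordinates(frames, ref)
          } else NULL
          n <- nFrames(maps)
          tsne_idx <- if (n > cfg$tsneMaxFrames) {
            set.seed(an_seed)
            sort(sample.int(n, cfg$tsneMaxFrames))
          } else seq_len(n)
          xy <- tsneProject(latentMu(emb)[tsne_idx, , drop = FALSE],
                            perplexity = min(cfg$perplexity,
                                             (length(tsne_idx) - 1) / 4),
                            seed = an_seed)
          st <- assignStates(latentMu(emb), k = cfg$k, seed = an_seed,
                             rmsd = rc$rmsd_A, q = rc$q_native)
          fes <- fesHistogram(xy, bins = cfg$bins)
          utils::write.csv(as.data.frame(fes), fes_path, row.names = FALSE)
          plotLandscape(fes, png_path)
          writeEmbeddings(emb, emb_path,
                          states = st$labels,
                          rmsd = rc$rmsd_A, q = rc$q_native)
          report <- list(
            config = list(seed = cfg$seed, preset = cfg$preset,
                          nFrames = cfg$nFrames, cutoff = cfg$cutoff,
                          epochs = cfg$epochs, k = cfg$k),
            misprediction_fraction = fractions,
            correct_fraction = lapply(fractions, function(f) 1 - f),
            states = st$summary,
            artifacts = list(maps = basename(maps_path),
                             model = basename(model_path),
                             loss_trace = basename(trace_path),
                             embeddings = basename(emb_path),
                             landscape = basename(fes_path)))
          jsonlite::write_json(report, report_path, auto_unbox = TRUE,
                               digits = NA, pretty = TRUE, na = "null")
        })

  # -- transfer ---------------------------------------------------------
  if (!use_real && !is.null(cfg$transferSeed)) {
    transfer_path <- file.path(out, "transfer.json")
    tr_par <- list(transferSeed = cfg$transferSeed)
    stage("transfer", hash_of(tr_par, c(maps_path, model_path)),
          transfer_path, function() {
            model <- loadModel(model_path)
            sim_cfg <- syntheticPreset(cfg$preset, nFrames = cfg$nFrames,
                                       seed = as.integer(cfg$transferSeed))
            trajB <- generateFoldingTrajectory(sim_cfg)
            mapsB <- padMaps(computeContactMaps(trajB@frames,
                                                cutoff = cfg$cutoff),
                             model@inputDim)
            res <- transferProject(model, mapsB,
                                   seed = stage_seed(cfg$seed, "transfer"))
            maps <- readContactMaps(maps_path)
            split <- splitDataset(nFrames(maps))
            held_out <- mispredictionFraction(
              reconstructionDifference(model, maps, subset = testIdx(split)))
            jsonlite::write_json(
              list(transfer_misprediction = res$mispredictionFraction,
                   heldout_misprediction = held_out,
                   ratio = res$mispredictionFraction / held_out),
              transfer_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
          })
  }

  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  report <- jsonlite::read_json(report_path, simplifyVector = TRUE)
  report$stages <- stages_run
  invisible(report)
}
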