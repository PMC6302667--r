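# Accessors and show methods.

#' @rdname TrajectoryFrames-class
#' @export
setMethod("nFrames", "TrajectoryFrames", function(x) dim(x@coords)[1])

#' @rdname TrajectoryFrames-class
#' @export
setMethod("nAtoms", "TrajectoryFrames", function(x) dim(x@coords)[2])

#' @rdname TrajectoryFrames-class
#' @export
setMethod("frameCoords", "TrajectoryFrames", function(x) x@coords)

setMethod("show", "TrajectoryFrames", function(object) {
  cat("TrajectoryFrames:", nFrames(object), "frames x", nAtoms(object),
      "C-alpha atoms")
  if (nzchar(object@sourceId)) cat(" [", object@sourceId, "]", sep = "")
  cat("\n")
})

#' @rdname ContactMapSeries-class
#' @export
setMethod("contactMaps", "ContactMapSeries", function(x) x@maps)

#' @rdname ContactMapSeries-class
#' @export
setMethod("nResidues", "ContactMapSeries", function(x) x@nResidues)

#' @rdname ContactMapSeries-class
#' @export
setMethod("mapSize", "ContactMapSeries", function(x) dim(x@maps)[1])

#' @rdname ContactMapSeries-class
#' @export
setMethod("nFrames", "ContactMapSeries", function(x) dim(x@maps)[3])

setMethod("show", "ContactMapSeries", function(object) {
  cat("ContactMapSeries:", nFrames(object), "frames,",
      object@nResidues, "residues,",
      sprintf("%dx%d maps (pad %d), cutoff %g A\n",
              mapSize(object), mapSize(object), object@pad, object@cutoff))
})

#' @rdname DatasetSplit-class
#' @export
setMethod("trainIdx", "DatasetSplit", function(x) x@trainIdx)

#' @rdname DatasetSplit-class
#' @export
setMethod("testIdx", "DatasetSplit", function(x) x@testIdx)

#' @rdname DatasetSplit-class
#' @export
setMethod("valIdx", "DatasetSplit", function(x) x@valIdx)

setMethod("show", "DatasetSplit", function(object) {
  cat(sprintf("DatasetSplit (%s): train %d / test %d / val %d\n",
              object@mode, length(object@trainIdx), length(object@testIdx),
              length(object@valIdx)))
})

#' @rdname NativeReference-class
#' @export
setMethod("nativeContacts", "NativeReference", function(x) x@nativeContacts)

#' @rdname NativeReference-class
#' @export
setMethod("nativeCoords", "NativeReference", function(x) x@coords)

setMethod("show", "NativeReference", function(object) {
  cat(sprintf(paste0("NativeReference: %d residues, %d native contacts ",
                     "(<%g A in >=%g%% of frames within %g A RMSD)\n"),
              nrow(object@coords), nrow(object@nativeContacts),
              object@contactCutoff, 100 * object@ensembleFraction,
              object@rmsdCutoff))
})

#' @rdname CVAEModel-class
#' @export
setMethod("hyperparams", "CVAEModel", function(x) x@hyperparams)

#' @rdname CVAEModel-class
#' @export
setMethod("lossTrace", "CVAEModel", function(x) x@lossTrace)

#' @rdname CVAEModel-class
#' @export
setMethod("latentDim", "CVAEModel", function(x) x@hyperparams$latentDim)

setMethod("show", "CVAEModel", function(object) {
  hp <- object@hyperparams
  cat(sprintf(paste0("CVAEModel: %dx%d input, %d conv layers x %d filters ",
                     "(%dx%d), dense %d, latent %d\n"),
              object@inputDim, object@inputDim, hp$nConvLayers, hp$nFilters,
              hp$kernel, hp$kernel, hp$nDense, hp$latentDim))
  if (object@trainedEpochs > 0) {
    last <- object@lossTrace[nrow(object@lossTrace), ]
    cat(sprintf("  trained %d epochs (%s, lr %g); last val L = %.3f\n",
                object@trainedEpochs, hp$optimizer, hp$learningRate,
                last$val_L))
  } else {
    cat("  untrained\n")
  }
})

#' @rdname LatentEmbedding-class
#' @export
setMethod("latentMu", "LatentEmbedding", function(x) x@mu)

#' @rdname LatentEmbedding-class
#' @export
setMethod("latentLogVar", "LatentEmbedding", function(x) x@logVar)

#' @rdname LatentEmbedding-class
#' @export
setMethod("latentZ", "LatentEmbedding", function(x) x@z)

#' @rdname LatentEmbedding-class
#' @export
setMethod("nFrames", "LatentEmbedding", function(x) nrow(x@mu))

setMethod("show", "LatentEmbedding", function(object) {
  cat("LatentEmbedding:", nrow(object@mu), "frames x", ncol(object@mu),
      "latent dimensions\n")
})

setMethod("show", "ReconstructionDiff", function(object) {
  d <- dim(object@diffs)
  cat(sprintf("ReconstructionDiff: %d frames of %dx%d pixels, threshold %g\n",
              d[3], d[1], d[2], object@threshold))
})

#' @rdname SyntheticTrajectory-class
#' @export
setMethod("stateLabels", "SyntheticTrajectory", function(x) x@labels)

#' @rdname SyntheticTrajectory-class
#' @export
setMethod("frameCoords", "SyntheticTrajectory", function(x) x@frames@coords)

#' @rdname SyntheticTrajectory-class
#' @export
setMethod("nFrames", "SyntheticTrajectory", function(x) nFrames(x@frames))

#' @rdname SyntheticTrajectory-class
#' @export
setMethod("nativeCoords", "SyntheticTrajectory", function(x) x@native)

setMethod("show", "SyntheticTrajectory", function(object) {
  cat(sprintf("SyntheticTrajectory: %d frames, %d residues, states: %s\n",
              nFrames(object), nAtoms(object@frames),
              paste(unique(object@labels), collapse = ", ")))
})
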