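#' @rdname TrajectoryFrames-class
#' @param x an object.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname TrajectoryFrames-class
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname TrajectoryFrames-class
#' @export
setGeneric("frameCoords", function(x) standardGeneric("frameCoords"))

#' @rdname ContactMapSeries-class
#' @param x an object.
#' @export
setGeneric("contactMaps", function(x) standardGeneric("contactMaps"))

#' @rdname ContactMapSeries-class
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' @rdname ContactMapSeries-class
#' @export
setGeneric("mapSize", function(x) standardGeneric("mapSize"))

#' @rdname DatasetSplit-class
#' @param x an object.
#' @export
setGeneric("trainIdx", function(x) standardGeneric("trainIdx"))

#' @rdname DatasetSplit-class
#' @export
setGeneric("testIdx", function(x) standardGeneric("testIdx"))

#' @rdname DatasetSplit-class
#' @export
setGeneric("valIdx", function(x) standardGeneric("valIdx"))

#' @rdname NativeReference-class
#' @param x an object.
#' @export
setGeneric("nativeContacts", function(x) standardGeneric("nativeContacts"))

#' @rdname NativeReference-class
#' @export
setGeneric("nativeCoords", function(x) standardGeneric("nativeCoords"))

#' @rdname CVAEModel-class
#' @param x an object.
#' @export
setGeneric("hyperparams", function(x) standardGeneric("hyperparams"))

#' @rdname CVAEModel-class
#' @export
setGeneric("lossTrace", function(x) standardGeneric("lossTrace"))

#' @rdname CVAEModel-class
#' @export
setGeneric("latentDim", function(x) standardGeneric("latentDim"))

#' @rdname LatentEmbedding-class
#' @param x an object.
#' @export
setGeneric("latentMu", function(x) standardGeneric("latentMu"))

#' @rdname LatentEmbedding-class
#' @export
setGeneric("latentLogVar", function(x) standardGeneric("latentLogVar"))

#' @rdname LatentEmbedding-class
#' @export
setGeneric("latentZ", function(x) standardGeneric("latentZ"))

#' @rdname SyntheticTrajectory-class
#' @param x an object.
#' @export
setGeneric("stateLabels", function(x) standardGeneric("stateLabels"))
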