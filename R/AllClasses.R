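#' @import methods
NULL

#' TrajectoryFrames: per-frame C-alpha coordinates
#'
#' Container for the C-alpha coordinate series of a molecular dynamics
#' trajectory (real or synthetic). Coordinates are stored as a
#' `frames x atoms x 3` array in Angstrom, in trajectory order.
#'
#' @slot coords numeric array, `nFrames x nAtoms x 3`, Angstrom.
#' @slot frameInterval time per frame (arbitrary units; metadata only).
#' @slot sourceId free-text label for the trajectory origin.
#'
#' @seealso [loadTrajectory()], [computeContactMaps()]
#' @export
setClass("TrajectoryFrames",
  representation(coords = "array", frameInterval = "numeric",
                 sourceId = "character"),
  prototype(frameInterval = 1, sourceId = ""))

setValidity("TrajectoryFrames", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[3] != 3L)
    return("coords must be a frames x atoms x 3 array")
  if (d[2] < 2L)
    return("at least 2 atoms per frame are required")
  if (d[1] > 0L && !all(is.finite(object@coords)))
    return("all coordinates must be finite")
  TRUE
})

#' ContactMapSeries: per-frame binary C-alpha contact maps
#'
#' Symmetric 0/1 contact matrices, one per trajectory frame, with entry
#' `(i, j) = 1` when atoms i and j lie strictly within the distance cutoff.
#' The diagonal is 1 (an atom is at distance 0 from itself). Maps may carry
#' zero padding (rows/columns `N+1 .. M`) so that convolutional models see a
#' fixed, even input size.
#'
#' @slot maps numeric array, `M x M x nFrames`, values in \{0, 1\}.
#' @slot nResidues number of real residues N (top-left `N x N` block).
#' @slot pad `M - N`.
#' @slot cutoff contact distance cutoff in Angstrom.
#'
#' @seealso [computeContactMaps()], [padMaps()]
#' @export
setClass("ContactMapSeries",
  representation(maps = "array", nResidues = "integer", pad = "integer",
                 cutoff = "numeric"))

setValidity("ContactMapSeries", function(object) {
  d <- dim(object@maps)
  if (length(d) != 3L || d[1] != d[2])
    return("maps must be an M x M x nFrames array")
  M <- d[1]; N <- object@nResidues
  if (M != N + object@pad)
    return("map size must equal nResidues + pad")
  if (object@cutoff <= 0)
    return("cutoff must be positive")
  m <- object@maps
  if (length(m) && !all(m == 0 | m == 1))
    return("map entries must be 0 or 1")
  if (d[3] > 0L) {
    if (!all(m == aperm(m, c(2, 1, 3))))
      return("maps must be symmetric")
    diags <- m[cbind(rep(seq_len(N), d[3]),
                     rep(seq_len(N), d[3]),
                     rep(seq_len(d[3]), each = N))]
    if (!all(diags == 1))
      return("diagonal entries of the unpadded block must be 1")
    if (object@pad > 0L && any(m[(N + 1):M, , ] != 0))
      return("padded rows/columns must be 0")
  }
  TRUE
})

#' DatasetSplit: disjoint train/test/validation frame indices
#'
#' @slot trainIdx,testIdx,valIdx integer frame indices (1-based), pairwise
#'   disjoint, jointly covering all frames.
#' @slot fractions the three requested proportions (sum to 1).
#' @slot mode `"contiguous"` or `"random"`.
#'
#' @seealso [splitDataset()]
#' @export
setClass("DatasetSplit",
  representation(trainIdx = "integer", testIdx = "integer",
                 valIdx = "integer", fractions = "numeric",
                 mode = "character"))

setValidity("DatasetSplit", function(object) {
  all_idx <- c(object@trainIdx, object@testIdx, object@valIdx)
  n <- length(all_idx)
  if (anyDuplicated(all_idx))
    return("train/test/val index sets must be pairwise disjoint")
  if (!setequal(all_idx, seq_len(n)))
    return("index sets must jointly cover 1..nFrames exactly once")
  if (length(object@fractions) != 3L ||
      abs(sum(object@fractions) - 1) > 1e-8)
    return("fractions must be three proportions summing to 1")
  TRUE
})

#' NativeReference: native structure, native contacts and thresholds
#'
#' The folded reference used by both reaction coordinates. `nativeContacts`
#' holds unordered residue pairs (sequence separation >= 3) that are in
#' contact (strictly under `contactCutoff`) in at least `ensembleFraction`
#' of the native ensemble: the frames within `rmsdCutoff` RMSD of the
#' native structure.
#'
#' @slot coords `N x 3` native C-alpha coordinates in Angstrom.
#' @slot nativeContacts two-column integer matrix of residue pairs (i < j).
#' @slot rmsdCutoff RMSD cutoff in Angstrom defining the native ensemble.
#' @slot ensembleFraction minimum contact frequency inside the ensemble.
#' @slot contactCutoff contact distance cutoff in Angstrom.
#'
#' @seealso [buildNativeReference()], [fractionNativeContacts()]
#' @export
setClass("NativeReference",
  representation(coords = "matrix", nativeContacts = "matrix",
                 rmsdCutoff = "numeric", ensembleFraction = "numeric",
                 contactCutoff = "numeric"),
  prototype(rmsdCutoff = 1.1, ensembleFraction = 0.75, contactCutoff = 8))

setValidity("NativeReference", function(object) {
  if (ncol(object@coords) != 3L)
    return("native coords must be an N x 3 matrix")
  nc <- object@nativeContacts
  if (nrow(nc) > 0) {
    if (ncol(nc) != 2L)
      return("nativeContacts must have two columns")
    if (any(nc < 1) || any(nc > nrow(object@coords)))
      return("nativeContacts indices out of range")
    if (any(nc[, 1] >= nc[, 2]))
      return("nativeContacts pairs must satisfy i < j")
  }
  TRUE
})

#' CVAEModel: architecture, weights and training trace
#'
#' State of the convolutional variational autoencoder: validated
#' hyperparameters, the (possibly untrained) weight set, the square input
#' size the model was built for, and the per-epoch loss trace accumulated
#' by [trainModel()].
#'
#' @slot hyperparams validated list from [cvaeHyperparams()].
#' @slot weights list of weight matrices (opaque; layout fixed by the
#'   hyperparameters).
#' @slot inputDim square input side M (padded map size).
#' @slot trainedEpochs number of epochs trained so far.
#' @slot lossTrace data.frame with one row per epoch: `epoch`, `train_L`,
#'   `train_Er`, `train_El`, `val_L`, `val_Er`, `val_El`.
#'
#' @seealso [buildModel()], [trainModel()], [encodeMaps()]
#' @export
setClass("CVAEModel",
  representation(hyperparams = "list", weights = "list",
                 inputDim = "integer", trainedEpochs = "integer",
                 lossTrace = "data.frame"))

#' LatentEmbedding: per-frame latent coordinates
#'
#' Encoder output: the Gaussian posterior mean and log-variance per frame,
#' plus one reparameterized sample `z = mu + exp(logVar/2) * eps`.
#'
#' @slot mu,logVar,z numeric `frames x d` matrices.
#' @export
setClass("LatentEmbedding",
  representation(mu = "matrix", logVar = "matrix", z = "matrix"))

setValidity("LatentEmbedding", function(object) {
  if (!all(dim(object@mu) == dim(object@logVar)) ||
      !all(dim(object@mu) == dim(object@z)))
    return("mu, logVar and z must have identical dimensions")
  if (length(object@mu) && !all(is.finite(cbind(object@mu, object@logVar))))
    return("latent values must be finite")
  TRUE
})

#' ReconstructionDiff: reconstructed-minus-original contact values
#'
#' Per-pixel difference between the decoded contact probability and the
#' original binary contact, restricted to the unpadded `N x N` block.
#' Values lie in `[-1, 1]`; a positive (negative) value means the model
#' overpredicts (underpredicts) a contact.
#'
#' @slot diffs numeric array `N x N x frames` in `[-1, 1]`.
#' @slot threshold misprediction tolerance on the `[0, 1]` contact scale.
#' @seealso [reconstructionDifference()], [mispredictionFraction()]
#' @export
setClass("ReconstructionDiff",
  representation(diffs = "array", threshold = "numeric"),
  prototype(threshold = 0.1))

setValidity("ReconstructionDiff", function(object) {
  if (length(object@diffs) &&
      (min(object@diffs) < -1 - 1e-9 || max(object@diffs) > 1 + 1e-9))
    return("reconstruction differences must lie in [-1, 1]")
  if (object@threshold <= 0 || object@threshold >= 1)
    return("threshold must lie in (0, 1)")
  TRUE
})

#' SyntheticTrajectory: generated frames with ground truth
#'
#' Output of the synthetic folding-trajectory generator: the coordinate
#' series, the per-frame ground-truth state label, the ideal native
#' structure and the generating configuration.
#'
#' @slot frames a [TrajectoryFrames-class] object.
#' @slot labels character vector of per-frame state names.
#' @slot native `N x 3` native C-alpha coordinates.
#' @slot config the [syntheticConfig()] list used for generation.
#' @seealso [generateFoldingTrajectory()]
#' @export
setClass("SyntheticTrajectory",
  representation(frames = "TrajectoryFrames", labels = "character",
                 native = "matrix", config = "list"))

setValidity("SyntheticTrajectory", function(object) {
  if (length(object@labels) != nFrames(object@frames))
    return("labels length must equal the number of frames")
  if (nrow(object@native) != nAtoms(object@frames))
    return("native must have the same atom count as the frames")
  TRUE
})
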