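# Reconstruction-quality evaluation on synthetic systems.

#' Evaluate CVAE reconstruction quality on a synthetic system
#'
#' Runs the full evaluation protocol on one generator preset: simulate a
#' four-state folding trajectory, compute 8 Angstrom contact maps, pad,
#' split 80/10/10 in contiguous blocks, train a latent-dim-3 CVAE with
#' RMSprop (batch size `|train|/100`), and score the percentage of
#' held-out unpadded pixels whose reconstruction lies within `threshold`
#' of the true binary value. Percentages are reported for both the test
#' and the validation partition.
#'
#' The default network (2 convolutional layers of 16 3x3 filters) and data
#' volume are sized for a single CPU core; all settings sit inside the
#' standard tuning bounds (see [cvaeHyperparams()]) and can be overridden.
#'
#' @param preset generator preset name (see [syntheticPreset()]).
#' @param nFrames number of frames to simulate.
#' @param epochs training epochs.
#' @param seed master seed; generation, initialization and training derive
#'   their seeds from it.
#' @param hyperparams named-list overrides for [cvaeHyperparams()].
#' @param threshold reconstruction tolerance on the contact scale.
#' @return list with `correctPctTest`, `correctPctVal` (percentages in
#'   0-100), `mispredictionTest`, `mispredictionVal`, and the underlying
#'   `model`, `maps`, `split` and `traj` objects.
#' @examples
#' \donttest{
#' res <- evaluateReconstruction(nFrames = 500, epochs = 5, seed = 1)
#' res$correctPctTest
#' }
#' @export
evaluateReconstruction <- function(preset = "fs21", nFrames = 3000,
                                   epochs = 30, seed = 7,
                                   hyperparams = list(nConvLayers = 2,
                                                      nFilters = 16,
                                                      kernel = 3,
                                                      nDense = 64,
                                                      latentDim = 3),
                                   threshold = 0.1) {
  cfg <- syntheticPreset(preset, nFrames = nFrames, seed = seed)
  traj <- generateFoldingTrajectory(cfg)
  maps <- padMaps(computeContactMaps(traj@frames))
  split <- splitDataset(nFrames(maps))
  hp <- do.call(cvaeHyperparams,
                utils::modifyList(hyperparams, list(epochs = epochs)))
  model <- buildModel(hp, mapSize(maps), seed = seed + 1)
  model <- trainModel(model, maps, split, seed = seed + 2, epochs = epochs)
  mis <- vapply(list(test = testIdx(split), val = valIdx(split)),
                function(idx) {
                  mispredictionFraction(reconstructionDifference(
                    model, maps, subset = idx, threshold = threshold))
                }, numeric(1))
  list(correctPctTest = 100 * (1 - mis[["test"]]),
       correctPctVal = 100 * (1 - mis[["val"]]),
       mispredictionTest = mis[["test"]],
       mispredictionVal = mis[["val"]],
       model = model, maps = maps, split = split, traj = traj)
}
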