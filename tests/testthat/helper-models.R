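# A small trained model shared by the diagnostic tests, trained once per
# test session. Two well-separated synthetic states, 300 frames, a few
# epochs: enough for the latent space to organize without slowing the
# suite down.

.model_cache <- new.env(parent = emptyenv())

small_trained_fixture <- function() {
  if (!is.null(.model_cache$fix)) return(.model_cache$fix)
  cfg <- syntheticConfig(
    nFrames = 300, seed = 101,
    states = list(
      list(name = "folded", q = 1.0, weight = 0.5),
      list(name = "unfolded", q = 0.1, weight = 0.5)),
    switchProb = 0.1)
  traj <- generateFoldingTrajectory(cfg)
  maps <- padMaps(computeContactMaps(traj@frames))
  split <- splitDataset(nFrames(maps))
  hp <- cvaeHyperparams(nConvLayers = 2, nFilters = 16, kernel = 3,
                        latentDim = 3)
  model <- buildModel(hp, mapSize(maps), seed = 7)
  model <- trainModel(model, maps, split, seed = 7, epochs = 8)
  .model_cache$fix <- list(traj = traj, maps = maps, split = split,
                           model = model)
  .model_cache$fix
}
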