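# Synthetic trajectory generator: determinism, state geometry, Markov
# occupancy and cross-module consistency.

test_that("generation is bit-identical for the same seed", {
  cfg <- syntheticConfig(nFrames = 50, seed = 13)
  a <- generateFoldingTrajectory(cfg)
  b <- generateFoldingTrajectory(cfg)
  expect_identical(frameCoords(a), frameCoords(b))
  expect_identical(stateLabels(a), stateLabels(b))
})

test_that("zero frames still return the native structure", {
  traj <- generateFoldingTrajectory(syntheticConfig(nFrames = 0, seed = 1))
  expect_equal(nFrames(traj), 0)
  expect_equal(nrow(nativeCoords(traj)), 21)
})

test_that("unreachable target q values are a configuration error", {
  cfg <- syntheticConfig(
    nResidues = 5, nFrames = 5, seed = 1,
    states = list(list(name = "odd", q = 0.66, weight = 1)))
  expect_error(generateFoldingTrajectory(cfg), "not reachable")
})

test_that("paired trajectories share the native structure but not the
           stochastic realization", {
  cfg <- syntheticConfig(nFrames = 40, seed = 21)
  pair <- generatePairedTrajectories(cfg, seed2 = 22)
  expect_identical(nativeCoords(pair[[1]]), nativeCoords(pair[[2]]))
  expect_false(identical(frameCoords(pair[[1]]), frameCoords(pair[[2]])))
  same <- generatePairedTrajectories(cfg, seed2 = 21)
  expect_identical(frameCoords(same[[1]]), frameCoords(same[[2]]))
})

test_that("folded frames sit near the native structure and unfolded frames
           far from it", {
  traj <- generateFoldingTrajectory(syntheticConfig(nFrames = 600, seed = 17))
  rmsd <- rmsdToNative(traj@frames, nativeCoords(traj))
  lab <- stateLabels(traj)
  expect_lte(mean(rmsd[lab == "folded"]), 1.5)
  expect_gt(mean(rmsd[lab == "unfolded"]), 1.5)
})

test_that("misfolded frames combine high Q with high RMSD and a contact map
           distinct from the folded state", {
  cfg <- syntheticConfig(
    nFrames = 200, seed = 19,
    states = list(list(name = "folded", q = 1, weight = 0.5),
                  list(name = "misfolded", weight = 0.5,
                       misfolded = TRUE)))
  traj <- generateFoldingTrajectory(cfg)
  ref <- buildNativeReference(nativeCoords(traj))
  rc <- reactionCoordinates(traj@frames, ref)
  lab <- stateLabels(traj)
  expect_gte(mean(rc$q_native[lab == "misfolded"]), 0.6)
  expect_gt(mean(rc$rmsd_A[lab == "misfolded"]),
            3 * mean(rc$rmsd_A[lab == "folded"]))
  # the misfolded contact pattern is distinguishable from the folded one
  maps <- computeContactMaps(traj@frames)
  mean_map <- function(which_lab)
    apply(contactMaps(maps)[, , lab == which_lab, drop = FALSE], 1:2, mean)
  expect_gt(mean(abs(mean_map("misfolded") - mean_map("folded"))), 0.01)
})

test_that("Markov-chain occupancy converges to the configured weights", {
  traj <- generateFoldingTrajectory(
    syntheticConfig(nFrames = 10000, seed = 23, switchProb = 0.2))
  occ <- table(stateLabels(traj)) / 10000
  w <- vapply(traj@config$states, `[[`, numeric(1), "weight")
  names(w) <- vapply(traj@config$states, `[[`, character(1), "name")
  w <- w / sum(w)
  expect_lt(max(abs(occ[names(w)] - w)), 0.05)
})

test_that("both paired trajectories recover the same native contact set
           from their folded frames", {
  cfg <- syntheticConfig(nFrames = 150, seed = 29)
  pair <- generatePairedTrajectories(cfg, seed2 = 31)
  refs <- lapply(pair, function(tr)
    buildNativeReference(nativeCoords(tr), tr@frames))
  expect_identical(nativeContacts(refs[[1]]), nativeContacts(refs[[2]]))
})
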