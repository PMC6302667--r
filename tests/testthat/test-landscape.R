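# Landscape diagnostics: reconstruction differences, misprediction
# fraction, t-SNE, -log histogram landscape and state assignment.

test_that("reconstruction differences are bounded and require a trained
           model", {
  fix <- small_trained_fixture()
  d <- reconstructionDifference(fix$model, fix$maps,
                                subset = testIdx(fix$split))
  expect_gte(min(d@diffs), -1)
  expect_lte(max(d@diffs), 1)
  expect_equal(dim(d@diffs)[1:2], c(21, 21))  # unpadded block only
  untrained <- buildModel(cvaeHyperparams(nConvLayers = 2, nFilters = 16,
                                          kernel = 3), 24)
  expect_error(reconstructionDifference(untrained, fix$maps), "untrained")
})

test_that("a well-trained model centers the difference histogram at zero", {
  fix <- small_trained_fixture()
  d <- reconstructionDifference(fix$model, fix$maps,
                                subset = testIdx(fix$split))
  expect_gte(mean(abs(d@diffs) <= 0.1), 0.85)
  expect_lt(abs(median(d@diffs)), 0.05)
})

test_that("misprediction counting is strict at the threshold and
           complements the correct fraction", {
  mk <- function(v) new("ReconstructionDiff",
                        diffs = array(v, c(2, 2, 1)), threshold = 0.1)
  expect_equal(mispredictionFraction(mk(rep(0, 4))), 0)
  # reconstructions (0.95, 0.05, 0.2, 0.3) of truths (1, 0, 1, 0)
  d <- mk(c(-0.05, 0.05, -0.8, 0.3))
  expect_equal(mispredictionFraction(d), 0.5)
  expect_equal(mispredictionFraction(d) + mean(abs(d@diffs) <= 0.1), 1)
  # exactly at the threshold counts as correct
  expect_equal(mispredictionFraction(mk(rep(0.10, 4))), 0)
})

test_that("t-SNE is seed-deterministic, separates well-separated blobs and
           tolerates degenerate input", {
  set.seed(41)
  blobs <- rbind(matrix(rnorm(150, 0, 0.3), 50, 3),
                 matrix(rnorm(150, 8, 0.3), 50, 3),
                 matrix(rnorm(150, -8, 0.3), 50, 3))
  truth <- rep(1:3, each = 50)
  y1 <- tsneProject(blobs, perplexity = 10, seed = 2, maxIter = 300)
  y2 <- tsneProject(blobs, perplexity = 10, seed = 2, maxIter = 300)
  expect_identical(y1, y2)
  km <- assignStates(y1, k = 3, seed = 2)
  expect_gte(purity(km$labels, truth), 0.95)

  flat <- matrix(1, 100, 3)
  yf <- tsneProject(flat, perplexity = 10, seed = 1, maxIter = 50)
  expect_true(all(is.finite(yf)))
  expect_error(tsneProject(blobs[1:20, ], perplexity = 10), "too few")
})

test_that("the -log histogram landscape is zero at the mode, masked when
           empty and invariant to duplicating the data", {
  xy <- cbind(c(rep(0, 100), rep(5, 10)), c(rep(0, 100), rep(5, 10)))
  fes <- fesHistogram(xy, bins = 4)
  expect_equal(min(fes, na.rm = TRUE), 0)
  # two occupied bins with counts 100 and 10: delta F = ln 10
  occupied <- sort(fes[!is.na(fes)])
  expect_equal(length(occupied), 2)
  expect_equal(occupied[2] - occupied[1], log(10), tolerance = 1e-9)
  # all mass in one bin
  one <- fesHistogram(cbind(rep(1, 7), rep(2, 7)), bins = 4)
  expect_equal(sum(!is.na(one)), 1)
  expect_equal(one[!is.na(one)], 0)
  # count-ratio invariance under duplication
  fes2 <- fesHistogram(rbind(xy, xy), bins = 4)
  expect_equal(as.vector(fes2), as.vector(fes), tolerance = 1e-12)
})

test_that("state assignment recovers generator labels, summarizes states
           and flags misfolded candidates", {
  fix <- small_trained_fixture()
  emb <- encodeMaps(fix$model, fix$maps, sample = FALSE)
  truth <- stateLabels(fix$traj)
  st <- assignStates(latentMu(emb), k = 2, seed = 3)
  expect_gte(purity(st$labels, truth), 0.9)
  expect_equal(sum(st$summary$population), nFrames(fix$maps))

  # k = 1: summaries equal global means
  ref <- buildNativeReference(nativeCoords(fix$traj))
  rc <- reactionCoordinates(fix$traj@frames, ref)
  g1 <- assignStates(latentMu(emb), k = 1, rmsd = rc$rmsd_A,
                     q = rc$q_native)
  expect_equal(g1$summary$meanQ, mean(rc$q_native))
  expect_equal(g1$summary$meanRmsd, mean(rc$rmsd_A))

  # weighted per-state means reproduce the global mean exactly
  st2 <- assignStates(latentMu(emb), k = 2, seed = 3, rmsd = rc$rmsd_A,
                      q = rc$q_native)
  wmean <- sum(st2$summary$meanQ * st2$summary$population) /
    sum(st2$summary$population)
  expect_equal(wmean, mean(rc$q_native), tolerance = 1e-9)

  expect_error(assignStates(latentMu(emb), k = nFrames(fix$maps) + 1),
               "exceeds")
})

test_that("a synthetic misfolded state is flagged as a misfolded
           candidate", {
  cfg <- syntheticConfig(
    nFrames = 200, seed = 43,
    states = list(list(name = "folded", q = 1, weight = 0.5),
                  list(name = "misfolded", weight = 0.5,
                       misfolded = TRUE)))
  traj <- generateFoldingTrajectory(cfg)
  ref <- buildNativeReference(nativeCoords(traj))
  rc <- reactionCoordinates(traj@frames, ref)
  maps <- computeContactMaps(traj@frames)
  # cluster on the raw maps (no model needed): the two states differ
  flat <- t(apply(contactMaps(maps), 3, identity))
  st <- assignStates(flat, k = 2, seed = 1, rmsd = rc$rmsd_A,
                     q = rc$q_native, qHi = 0.6, rHi = 3)
  expect_equal(sum(st$summary$misfoldedCandidate), 1)
  flagged <- which(st$summary$misfoldedCandidate)
  truth_state <- names(which.max(table(
    stateLabels(traj)[st$labels == flagged])))
  expect_equal(truth_state, "misfolded")
})
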