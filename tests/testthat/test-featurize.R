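# Trajectory reading, contact maps, padding and dataset splits.

test_that("single-frame PDB of 3 atoms reads back as 1 frame x 3 atoms", {
  coords <- array(c(0, 3.8, 7.6, 0, 0, 0, 0, 0, 0), c(1, 3, 3))
  pdb <- tempfile(fileext = ".pdb")
  writeTrajectoryPDB(coords, pdb)
  frames <- loadTrajectory(pdb)
  expect_equal(nFrames(frames), 1)
  expect_equal(nAtoms(frames), 3)
  expect_equal(frameCoords(frames), coords, tolerance = 1e-6)
})

test_that("trajectories round-trip through PDB and DCD files", {
  traj <- generateFoldingTrajectory(syntheticConfig(nFrames = 6, seed = 4))
  dir_pdb <- tempfile()
  paths <- writeSyntheticTrajectory(traj, dir_pdb, trajFormat = "pdb")
  reread <- loadTrajectory(paths["native"], paths["trajectory"])
  expect_equal(nFrames(reread), 6)
  # PDB stores 3 decimals -> 1e-2 A round-trip tolerance
  expect_lt(max(abs(frameCoords(reread) - frameCoords(traj))), 1e-2)

  dir_dcd <- tempfile()
  paths <- writeSyntheticTrajectory(traj, dir_dcd, trajFormat = "dcd")
  reread <- loadTrajectory(paths["native"], paths["trajectory"])
  expect_equal(nFrames(reread), 6)
  # DCD stores single precision
  expect_lt(max(abs(frameCoords(reread) - frameCoords(traj))), 1e-3)
})

test_that("empty atom selections and missing files are rejected", {
  # topology whose only atoms are CB -> no C-alpha to select
  pdb <- tempfile(fileext = ".pdb")
  writeLines(c(
    paste0("ATOM      1  CB  ALA A   1       0.000   0.000   0.000",
           "  1.00  0.00"),
    paste0("ATOM      2  CB  ALA A   2       3.800   0.000   0.000",
           "  1.00  0.00"),
    "END"), pdb)
  expect_error(loadTrajectory(pdb), "no atoms")
  expect_error(loadTrajectory(tempfile(fileext = ".pdb")), "not found")
})

test_that("contact cutoff is strict: 7.99 A in contact, 8.00 A not", {
  mk <- function(d) new("TrajectoryFrames",
                        coords = array(c(0, d, 0, 0, 0, 0), c(1, 2, 3)))
  expect_equal(contactMaps(computeContactMaps(mk(7.99)))[1, 2, 1], 1)
  expect_equal(contactMaps(computeContactMaps(mk(8.00)))[1, 2, 1], 0)
})

test_that("collinear atoms 10 A apart give the identity map", {
  frames <- new("TrajectoryFrames",
                coords = array(c(0, 10, 20, rep(0, 6)), c(1, 3, 3)))
  expect_equal(contactMaps(computeContactMaps(frames))[, , 1], diag(3))
})

test_that("contact maps equal the brute-force loop and are rigid-motion
           invariant on 100 random frames", {
  set.seed(11)
  for (f in 1:100) {
    coords <- matrix(rnorm(21 * 3, sd = 6), 21, 3)
    frames <- new("TrajectoryFrames", coords = array(coords, c(1, 21, 3)))
    fast <- contactMaps(computeContactMaps(frames))[, , 1]
    expect_identical(fast, brute_contact_map(coords))
    moved <- coords %*% t(random_rotation_matrix()) +
      matrix(runif(3, -50, 50), 21, 3, byrow = TRUE)
    moved_map <- contactMaps(computeContactMaps(
      new("TrajectoryFrames", coords = array(moved, c(1, 21, 3)))))[, , 1]
    expect_identical(moved_map, fast)
  }
})

test_that("padding preserves the original block and round-trips", {
  traj <- generateFoldingTrajectory(syntheticConfig(nFrames = 50, seed = 9))
  maps <- computeContactMaps(traj@frames)
  padded <- padMaps(maps, 24)
  expect_equal(mapSize(padded), 24)
  expect_identical(contactMaps(padded)[1:21, 1:21, ], contactMaps(maps))
  expect_true(all(contactMaps(padded)[22:24, , ] == 0))
  expect_identical(contactMaps(unpadMaps(padded)), contactMaps(maps))
  # target == N leaves the series untouched
  expect_identical(padMaps(maps, 21), maps)
  expect_error(padMaps(maps, 20), "smaller than")
})

test_that("default padded size is the smallest multiple of 4 at or above N", {
  expect_equal(defaultPaddedSize(21), 24)
  expect_equal(defaultPaddedSize(24), 24)
  expect_equal(defaultPaddedSize(25), 28)
})

test_that("80/10/10 split of 10 frames gives sizes (8, 1, 1)", {
  sp <- splitDataset(10)
  expect_equal(length(trainIdx(sp)), 8)
  expect_equal(length(testIdx(sp)), 1)
  expect_equal(length(valIdx(sp)), 1)
})

test_that("degenerate fractions and too-small inputs are rejected", {
  expect_error(splitDataset(10, fractions = c(1, 0, 0)), "positive")
  expect_error(splitDataset(5), "at least one frame")
})

test_that("random splits partition the frames and are seed-reproducible", {
  a <- splitDataset(1000, mode = "random", seed = 77)
  b <- splitDataset(1000, mode = "random", seed = 77)
  expect_identical(trainIdx(a), trainIdx(b))
  expect_identical(testIdx(a), testIdx(b))
  expect_identical(valIdx(a), valIdx(b))
  all_idx <- c(trainIdx(a), testIdx(a), valIdx(a))
  expect_setequal(all_idx, 1:1000)
  expect_equal(length(all_idx), 1000)  # no duplicates
  c_ <- splitDataset(1000, mode = "random", seed = 78)
  expect_false(identical(trainIdx(a), trainIdx(c_)))
})

test_that("contact-map cache round-trips", {
  traj <- generateFoldingTrajectory(syntheticConfig(nFrames = 5, seed = 2))
  maps <- padMaps(computeContactMaps(traj@frames))
  path <- tempfile(fileext = ".rds")
  writeContactMaps(maps, path)
  back <- readContactMaps(path)
  expect_identical(contactMaps(back), contactMaps(maps))
  expect_equal(back@cutoff, maps@cutoff)
})
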