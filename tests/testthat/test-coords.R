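# Reaction coordinates: Kabsch RMSD and fraction of native contacts.

test_that("RMSD is zero for identical and rigidly moved structures", {
  set.seed(21)
  native <- matrix(rnorm(15, sd = 4), 5, 3)
  expect_lt(rmsdToNative(frames_array(native), native), 1e-6)
  Rz90 <- euler_rotation(pi / 2, 0, 0)
  moved <- native %*% t(Rz90) + matrix(5, 5, 3)
  expect_lt(rmsdToNative(frames_array(moved), native), 1e-6)
})

test_that("RMSD matches a rotation-grid brute-force oracle on random
           5-atom pairs", {
  set.seed(22)
  for (rep in 1:5) {
    A <- matrix(rnorm(15, sd = 3), 5, 3)
    B <- matrix(rnorm(15, sd = 3), 5, 3)
    expect_equal(rmsdToNative(frames_array(A), B),
                 rmsd_rotation_oracle(A, B), tolerance = 1e-3)
  }
})

test_that("RMSD is symmetric and invariant under rigid motions of either
           argument", {
  set.seed(23)
  A <- matrix(rnorm(24, sd = 3), 8, 3)
  B <- matrix(rnorm(24, sd = 3), 8, 3)
  r0 <- rmsdToNative(frames_array(A), B)
  expect_equal(rmsdToNative(frames_array(B), A), r0, tolerance = 1e-9)
  for (rep in 1:5) {
    RA <- A %*% t(random_rotation_matrix()) +
      matrix(runif(3, -9, 9), 8, 3, byrow = TRUE)
    RB <- B %*% t(random_rotation_matrix()) +
      matrix(runif(3, -9, 9), 8, 3, byrow = TRUE)
    expect_equal(rmsdToNative(frames_array(RA), RB), r0, tolerance = 1e-9)
  }
})

test_that("all-coincident coordinates give RMSD 0 with a warning", {
  degen <- matrix(1, 4, 3)
  ref <- matrix(rnorm(12), 4, 3)
  expect_warning(r <- rmsdToNative(frames_array(degen), ref), "degenerate")
  expect_equal(r, 0)
})

test_that("atom-count mismatches are rejected", {
  expect_error(rmsdToNative(frames_array(matrix(0, 4, 3)),
                            matrix(0, 5, 3)), "does not match")
})

test_that("a single-frame ensemble reproduces the native frame's contacts", {
  native <- native_coords_for_tests(12)
  ref_direct <- buildNativeReference(native)
  ref_ens <- buildNativeReference(native, frames_array(native))
  expect_identical(nativeContacts(ref_ens), nativeContacts(ref_direct))
})

test_that("the 75% ensemble-frequency threshold is applied pair by pair", {
  # 8 atoms; pair (2,7) in contact in 3/4 frames (included at 75%),
  # pair (1,6) in 2/4 frames (excluded). All frames within 1.1 A RMSD.
  base <- cbind(c(0, 3, 6, 9, 9, 6, 3, 0),
                c(0, 1, 0, 1, 6, 5, 8.5, 7),
                rep(0, 8))
  d27 <- function(x) sqrt(sum((x[2, ] - x[7, ])^2))
  d16 <- function(x) sqrt(sum((x[1, ] - x[6, ])^2))
  stopifnot(d27(base) < 8, d16(base) < 8)        # both in contact natively
  f_break27 <- base; f_break27[7, 2] <- base[7, 2] + 1.2
  f_break16 <- base; f_break16[6, 2] <- base[6, 2] + 1.2
  stopifnot(d27(f_break27) > 8, d16(f_break16) > 8)
  ens <- frames_array(base, f_break16, f_break16, f_break27)
  ref <- buildNativeReference(base, ens)
  pairs <- nativeContacts(ref)
  has <- function(i, j) any(pairs[, 1] == i & pairs[, 2] == j)
  expect_true(has(2, 7))    # 3/4 frames = 75%
  expect_false(has(1, 6))   # 2/4 frames = 50%
})

test_that("an entirely unfolded ensemble falls back to the native frame's
           contacts with a warning", {
  native <- native_coords_for_tests(10)
  far <- frames_array(native * 3 + 20)
  expect_warning(ref <- buildNativeReference(native, far), "falling back")
  expect_identical(nativeContacts(ref),
                   nativeContacts(buildNativeReference(native)))
})

test_that("Q is 1 on the native frame, counts realized pairs, and is 0 for
           an extended chain", {
  native <- native_coords_for_tests(12)
  ref <- buildNativeReference(native)
  expect_equal(fractionNativeContacts(frames_array(native), ref), 1)

  # toy reference with exactly 4 native pairs, frame realizing exactly 3
  toy <- new("NativeReference", coords = native,
             nativeContacts = matrix(c(1L, 4L, 2L, 5L, 3L, 6L, 1L, 7L),
                                     ncol = 2, byrow = TRUE),
             rmsdCutoff = 1.1, ensembleFraction = 0.75, contactCutoff = 8)
  frame <- native
  frame[7, ] <- frame[7, ] + c(0, 30, 0)  # break (1,7) only
  expect_equal(fractionNativeContacts(frames_array(frame), toy), 0.75)

  extended <- cbind(seq(0, by = 10, length.out = 12), 0, 0)
  expect_equal(fractionNativeContacts(frames_array(extended), ref), 0)
})

test_that("empty native-contact sets are a configuration error", {
  ref <- new("NativeReference", coords = matrix(0, 4, 3),
             nativeContacts = matrix(integer(0), ncol = 2),
             rmsdCutoff = 1.1, ensembleFraction = 0.75, contactCutoff = 8)
  expect_error(fractionNativeContacts(frames_array(matrix(0, 4, 3)), ref),
               "empty")
})

test_that("Q separates generator-labeled folded from unfolded frames", {
  traj <- generateFoldingTrajectory(syntheticConfig(nFrames = 300, seed = 5))
  ref <- buildNativeReference(nativeCoords(traj))
  q <- fractionNativeContacts(traj@frames, ref)
  lab <- stateLabels(traj)
  expect_gte(mean(q[lab == "folded"]) - mean(q[lab == "unfolded"]), 0.5)
})
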