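# Reaction coordinates: RMSD to native (Kabsch) and fraction of native
# contacts Q.

# Optimal-superposition RMSD between two N x 3 coordinate sets.
# Both are centered at their centroids; the optimal proper rotation comes
# from the Kabsch SVD procedure with the det = +1 sign correction, so
# reflections are never used.
kabsch_rmsd <- function(A, B) {
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  H <- crossprod(A, B)           # 3x3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  diffs <- A %*% t(R) - B
  sqrt(sum(diffs^2) / nrow(A))
}

#' RMSD to the native structure
#'
#' Minimal root-mean-square deviation of each frame's C-alpha coordinates
#' from the native reference over all rigid superpositions (Kabsch/SVD with
#' proper-rotation correction). Invariant under rigid motions of either
#' argument and symmetric in the two structures.
#'
#' @param frames a [TrajectoryFrames-class] object (or `frames x N x 3`
#'   array).
#' @param native a [NativeReference-class] or an `N x 3` coordinate matrix.
#' @return numeric vector of per-frame RMSD values in Angstrom.
#' @examples
#' traj <- generateFoldingTrajectory(syntheticConfig(nFrames = 20, seed = 1))
#' rmsd <- rmsdToNative(traj@frames, traj@native)
#' @export
rmsdToNative <- function(frames, native) {
  coords <- if (is(frames, "TrajectoryFrames")) frames@coords else frames
  ref <- if (is(native, "NativeReference")) native@coords else native
  if (dim(coords)[2] != nrow(ref))
    stop("frame atom count (", dim(coords)[2],
         ") does not match native atom count (", nrow(ref), ")")
  nf <- dim(coords)[1]
  out <- numeric(nf)
  degenerate <- FALSE
  for (f in seq_len(nf)) {
    A <- coords[f, , ]
    if (all(abs(sweep(A, 2, colMeans(A))) < 1e-12)) {
      degenerate <- TRUE
      out[f] <- 0
      next
    }
    out[f] <- kabsch_rmsd(A, ref)
  }
  if (degenerate)
    warning("degenerate (all-coincident) coordinates in at least one frame; ",
            "returning 0 for those frames")
  out
}

# Unordered residue pairs with sequence separation >= minSeqSep that are in
# contact (strict < cutoff) in a single N x 3 structure.
contact_pairs <- function(coords, cutoff = 8, minSeqSep = 3) {
  d <- as.matrix(stats::dist(coords))
  sep <- abs(row(d) - col(d))
  hit <- which(d < cutoff & sep >= minSeqSep & upper.tri(d), arr.ind = TRUE)
  colnames(hit) <- NULL
  hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
}

#' Build a native-contact reference
#'
#' Defines the native ensemble as the frames of `ensemble` whose RMSD to
#' `nativeCoords` is at most `rmsdCutoff` (default 1.1 Angstrom), then calls
#' a residue pair native when it is in contact (strictly under
#' `contactCutoff`, default 8 Angstrom) in at least `ensembleFraction`
#' (default 75%) of those frames. Pairs closer than `minSeqSep` in sequence
#' are excluded: chain connectivity keeps them within the cutoff in every
#' conformation, so they carry no folding information. If no ensemble is
#' given, or no frame qualifies, the contacts of `nativeCoords` alone are
#' used (with a warning in the empty-ensemble case).
#'
#' @param nativeCoords `N x 3` native C-alpha coordinates.
#' @param ensemble optional [TrajectoryFrames-class] (or array) sampling the
#'   native basin.
#' @param rmsdCutoff RMSD cutoff (Angstrom) defining the native ensemble.
#' @param ensembleFraction minimum in-ensemble contact frequency.
#' @param contactCutoff contact distance cutoff (Angstrom, strict `<`).
#' @param minSeqSep minimum sequence separation |i - j| of native pairs.
#' @return a [NativeReference-class].
#' @export
buildNativeReference <- function(nativeCoords, ensemble = NULL,
                                 rmsdCutoff = 1.1, ensembleFraction = 0.75,
                                 contactCutoff = 8, minSeqSep = 3) {
  nativeCoords <- as.matrix(nativeCoords)
  fallback <- function() contact_pairs(nativeCoords, contactCutoff, minSeqSep)
  if (is.null(ensemble)) {
    pairs <- fallback()
  } else {
    coords <- if (is(ensemble, "TrajectoryFrames")) ensemble@coords
              else ensemble
    if (dim(coords)[1] == 0)
      stop("ensemble is empty")
    rmsd <- rmsdToNative(coords, nativeCoords)
    keep <- which(rmsd <= rmsdCutoff)
    if (length(keep) == 0) {
      warning("no ensemble frame within ", rmsdCutoff,
              " A of the native structure; falling back to the contacts ",
              "of the native structure itself")
      pairs <- fallback()
    } else {
      N <- nrow(nativeCoords)
      freq <- matrix(0, N, N)
      for (f in keep) {
        d <- as.matrix(stats::dist(coords[f, , ]))
        freq <- freq + (d < contactCutoff)
      }
      freq <- freq / length(keep)
      sep <- abs(row(freq) - col(freq))
      hit <- which(freq >= ensembleFraction & sep >= minSeqSep &
                     upper.tri(freq), arr.ind = TRUE)
      colnames(hit) <- NULL
      pairs <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    }
  }
  new("NativeReference", coords = nativeCoords,
      nativeContacts = matrix(as.integer(pairs), ncol = 2),
      rmsdCutoff = rmsdCutoff, ensembleFraction = ensembleFraction,
      contactCutoff = contactCutoff)
}

#' Fraction of native contacts Q
#'
#' Per-frame proportion of the native contact pairs that are realized
#' (strictly under the reference's contact cutoff) in the frame. Q is 1 for
#' the native structure itself and near 0 for fully extended chains.
#'
#' @param frames a [TrajectoryFrames-class] object (or `frames x N x 3`
#'   array).
#' @param native a [NativeReference-class] with a non-empty contact set.
#' @return numeric vector of per-frame Q values in `[0, 1]`.
#' @export
fractionNativeContacts <- function(frames, native) {
  stopifnot(is(native, "NativeReference"))
  pairs <- native@nativeContacts
  if (nrow(pairs) == 0)
    stop("native contact set is empty")
  coords <- if (is(frames, "TrajectoryFrames")) frames@coords else frames
  if (dim(coords)[2] != nrow(native@coords))
    stop("frame atom count does not match the native reference")
  nf <- dim(coords)[1]
  cutoff <- native@contactCutoff
  out <- numeric(nf)
  for (f in seq_len(nf)) {
    xi <- coords[f, pairs[, 1], ]
    xj <- coords[f, pairs[, 2], ]
    d <- sqrt(rowSums((xi - xj)^2))
    out[f] <- mean(d < cutoff)
  }
  out
}

#' Per-frame reaction-coordinate table
#'
#' Convenience wrapper returning both validation coordinates as a
#' data.frame with columns `frame`, `rmsd_A` and `q_native`.
#'
#' @inheritParams fractionNativeContacts
#' @return data.frame with one row per frame.
#' @export
reactionCoordinates <- function(frames, native) {
  stopifnot(is(native, "NativeReference"))
  data.frame(frame = seq_len(if (is(frames, "TrajectoryFrames"))
                               nFrames(frames) else dim(frames)[1]),
             rmsd_A = rmsdToNative(frames, native),
             q_native = fractionNativeContacts(frames, native))
}
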