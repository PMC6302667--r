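# Featurization: trajectory reading, contact maps, padding, splits.

#' Read C-alpha coordinates from a trajectory
#'
#' Reads a topology (PDB) and, optionally, a separate coordinate file and
#' returns the C-alpha coordinate series. Supported coordinate formats are
#' multi-model PDB and (CHARMM/NAMD-style) DCD, both read through
#' \pkg{bio3d}. When `coordinatePath` is `NULL`, frames are taken from the
#' topology file itself (useful for single-structure or multi-model PDBs).
#'
#' @param topologyPath path to a PDB file defining the atom content.
#' @param coordinatePath optional path to a multi-model PDB or DCD file with
#'   the frame coordinates.
#' @param selection atom selection; currently `"calpha"` (the default) or
#'   `"all"`, resolved with [bio3d::atom.select()].
#' @return a [TrajectoryFrames-class] object (coordinates in Angstrom, frame
#'   order preserved).
#' @examples
#' traj <- generateFoldingTrajectory(syntheticConfig(nFrames = 5, seed = 1))
#' pdb <- tempfile(fileext = ".pdb")
#' writeTrajectoryPDB(traj@frames, pdb)
#' loadTrajectory(pdb)
#' @export
loadTrajectory <- function(topologyPath, coordinatePath = NULL,
                           selection = "calpha") {
  if (!file.exists(topologyPath))
    stop("topology file not found: ", topologyPath)
  pdb <- bio3d::read.pdb(topologyPath, multi = TRUE, verbose = FALSE)
  sel <- bio3d::atom.select(pdb, selection, verbose = FALSE)
  n_sel <- length(sel$atom)
  if (n_sel == 0)
    stop("selection '", selection, "' matches no atoms in ", topologyPath)
  if (n_sel < 2)
    stop("selection must resolve to at least 2 atoms")
  if (is.null(coordinatePath)) {
    xyz <- pdb$xyz[, sel$xyz, drop = FALSE]
  } else {
    if (!file.exists(coordinatePath))
      stop("coordinate file not found: ", coordinatePath)
    ext <- tolower(tools::file_ext(coordinatePath))
    if (ext == "dcd") {
      xyz <- bio3d::read.dcd(coordinatePath, verbose = FALSE)
    } else if (ext %in% c("pdb", "ent")) {
      xyz <- bio3d::read.pdb(coordinatePath, multi = TRUE, verbose = FALSE)$xyz
    } else {
      stop("unsupported coordinate format '.", ext,
           "' (supported: multi-model PDB, DCD)")
    }
    n_total <- ncol(pdb$xyz) / 3
    if (ncol(xyz) != 3 * n_total)
      stop("atom count mismatch: topology has ", n_total,
           " atoms but coordinate frames have ", ncol(xyz) / 3)
    xyz <- xyz[, sel$xyz, drop = FALSE]
  }
  if (any(!is.finite(xyz)))
    stop("non-finite coordinates in trajectory")
  nf <- nrow(xyz)
  coords <- array(0, c(nf, n_sel, 3))
  for (a in seq_len(n_sel)) {
    coords[, a, 1] <- xyz[, 3 * a - 2]
    coords[, a, 2] <- xyz[, 3 * a - 1]
    coords[, a, 3] <- xyz[, 3 * a]
  }
  new("TrajectoryFrames", coords = coords, frameInterval = 1,
      sourceId = basename(if (is.null(coordinatePath)) topologyPath
                          else coordinatePath))
}

#' Write a coordinate series as a multi-model PDB
#'
#' One `MODEL`/`ENDMDL` block per frame, atoms written as alanine C-alphas.
#' Round-trips through [loadTrajectory()] at PDB precision (0.001 A).
#'
#' @param frames a [TrajectoryFrames-class] object or `frames x N x 3` array.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeTrajectoryPDB <- function(frames, path) {
  coords <- if (is(frames, "TrajectoryFrames")) frames@coords else frames
  nf <- dim(coords)[1]; na <- dim(coords)[2]
  xyz <- matrix(0, nf, 3 * na)
  xyz[, seq(1, 3 * na, 3)] <- coords[, , 1]
  xyz[, seq(2, 3 * na, 3)] <- coords[, , 2]
  xyz[, seq(3, 3 * na, 3)] <- coords[, , 3]
  bio3d::write.pdb(file = path, xyz = bio3d::as.xyz(xyz),
                   resno = seq_len(na), resid = rep("ALA", na),
                   elety = rep("CA", na), chain = rep("A", na))
  invisible(path)
}

#' Write a coordinate series as a DCD file
#'
#' Minimal single-precision CHARMM-format DCD writer (no unit cell), readable
#' by [bio3d::read.dcd()] and standard MD tooling. Exists so the synthetic
#' generator can exercise the full binary-trajectory reading path.
#'
#' @inheritParams writeTrajectoryPDB
#' @return `path`, invisibly.
#' @export
writeTrajectoryDCD <- function(frames, path) {
  coords <- if (is(frames, "TrajectoryFrames")) frames@coords else frames
  nf <- dim(coords)[1]; na <- dim(coords)[2]
  con <- file(path, "wb")
  on.exit(close(con))
  rec <- function(write_body, nbytes) {
    writeBin(as.integer(nbytes), con, size = 4, endian = "little")
    write_body()
    writeBin(as.integer(nbytes), con, size = 4, endian = "little")
  }
  icntrl <- integer(20)
  icntrl[1] <- nf      # number of frames
  icntrl[2] <- 1L      # first step
  icntrl[3] <- 1L      # save interval
  icntrl[4] <- nf      # number of steps
  icntrl[20] <- 24L    # CHARMM version stamp
  rec(function() {
    writeChar("CORD", con, nchars = 4, eos = NULL)
    writeBin(icntrl, con, size = 4, endian = "little")
  }, 84)
  title <- sprintf("%-80s", "generated by foldcvae")
  rec(function() {
    writeBin(1L, con, size = 4, endian = "little")
    writeChar(title, con, nchars = 80, eos = NULL)
  }, 84)
  rec(function() writeBin(as.integer(na), con, size = 4, endian = "little"), 4)
  for (f in seq_len(nf)) {
    for (ax in 1:3) {
      rec(function() writeBin(as.numeric(coords[f, , ax]), con, size = 4,
                              endian = "little"), 4 * na)
    }
  }
  invisible(path)
}

#' Compute binary C-alpha contact maps
#'
#' Entry `(i, j)` is 1 iff the Euclidean distance between atoms i and j is
#' strictly below `cutoff` (default 8 Angstrom). Maps are symmetric with a
#' unit diagonal, and -- being built from pairwise distances -- invariant
#' under any rigid rotation/translation of the frame.
#'
#' @param frames a [TrajectoryFrames-class] object.
#' @param cutoff contact distance cutoff in Angstrom (strict `<`).
#' @return an unpadded [ContactMapSeries-class] (`M = N`).
#' @examples
#' traj <- generateFoldingTrajectory(syntheticConfig(nFrames = 10, seed = 1))
#' maps <- computeContactMaps(traj@frames)
#' @export
computeContactMaps <- function(frames, cutoff = 8.0) {
  stopifnot(is(frames, "TrajectoryFrames"))
  if (cutoff <= 0)
    stop("cutoff must be positive")
  coords <- frames@coords
  if (length(coords) && any(!is.finite(coords)))
    stop("non-finite coordinates")
  nf <- dim(coords)[1]; na <- dim(coords)[2]
  maps <- array(0, c(na, na, nf))
  for (f in seq_len(nf)) {
    d <- as.matrix(stats::dist(coords[f, , ]))
    maps[, , f] <- 1 * (d < cutoff)
  }
  new("ContactMapSeries", maps = maps, nResidues = as.integer(na),
      pad = 0L, cutoff = cutoff)
}

#' Default padded map size
#'
#' Smallest even integer `>= n` divisible by 4, so that one stride-2
#' downsample keeps whole pixels and layer shapes stay clean.
#' @param n number of residues.
#' @return integer target size.
#' @export
defaultPaddedSize <- function(n) as.integer(4 * ceiling(n / 4))

#' Zero-pad contact maps to a fixed square size
#'
#' The original `N x N` block is preserved in the top-left corner; appended
#' rows/columns are zero.
#'
#' @param series a [ContactMapSeries-class].
#' @param target padded size `M >= N` (even). Defaults to
#'   [defaultPaddedSize()] of the residue count.
#' @return a padded [ContactMapSeries-class].
#' @export
padMaps <- function(series, target = defaultPaddedSize(nResidues(series))) {
  stopifnot(is(series, "ContactMapSeries"))
  N <- nResidues(series)
  M0 <- mapSize(series)
  target <- as.integer(target)
  if (target < N)
    stop("target size ", target, " is smaller than residue count ", N)
  if (target == M0)
    return(series)
  nf <- nFrames(series)
  maps <- array(0, c(target, target, nf))
  maps[seq_len(N), seq_len(N), ] <- series@maps[seq_len(N), seq_len(N), ]
  new("ContactMapSeries", maps = maps, nResidues = N,
      pad = as.integer(target - N), cutoff = series@cutoff)
}

#' Remove padding from contact maps
#' @param series a padded [ContactMapSeries-class].
#' @return the unpadded series (`M = N`).
#' @export
unpadMaps <- function(series) {
  stopifnot(is(series, "ContactMapSeries"))
  N <- nResidues(series)
  if (series@pad == 0L)
    return(series)
  new("ContactMapSeries", maps = series@maps[seq_len(N), seq_len(N), ,
                                             drop = FALSE],
      nResidues = N, pad = 0L, cutoff = series@cutoff)
}

#' Split frames into train/test/validation sets
#'
#' Default proportions are 80/10/10. `|train| = floor(f_train * n)`; the
#' remainder is split as evenly as possible between test and validation
#' (ties go to test). `"contiguous"` (the default) assigns consecutive
#' blocks in trajectory order, which avoids temporal leakage between
#' partitions; `"random"` permutes frames first (seeded).
#'
#' @param nFrames total number of frames.
#' @param fractions three positive proportions summing to 1.
#' @param mode `"contiguous"` or `"random"`.
#' @param seed integer seed (used in random mode).
#' @return a [DatasetSplit-class].
#' @examples
#' splitDataset(10)  # sizes 8 / 1 / 1
#' @export
splitDataset <- function(nFrames, fractions = c(0.8, 0.1, 0.1),
                         mode = c("contiguous", "random"), seed = 1) {
  mode <- match.arg(mode)
  nFrames <- as.integer(nFrames)
  if (length(fractions) != 3 || any(fractions <= 0))
    stop("fractions must be three positive proportions")
  if (abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must sum to 1")
  n_train <- floor(fractions[1] * nFrames)
  rem <- nFrames - n_train
  n_test <- ceiling(rem * fractions[2] / (fractions[2] + fractions[3]))
  n_val <- rem - n_test
  if (n_train < 1 || n_test < 1 || n_val < 1)
    stop("nFrames = ", nFrames,
         " is too small to give each partition at least one frame")
  idx <- seq_len(nFrames)
  if (mode == "random") {
    set.seed(seed)
    idx <- sample.int(nFrames)
  }
  new("DatasetSplit",
      trainIdx = as.integer(idx[seq_len(n_train)]),
      testIdx = as.integer(idx[n_train + seq_len(n_test)]),
      valIdx = as.integer(idx[n_train + n_test + seq_len(n_val)]),
      fractions = fractions, mode = mode)
}

#' Write / read a contact-map cache
#'
#' Serializes a [ContactMapSeries-class] to a single compressed cache file
#' (native R serialization) and reads it back.
#'
#' @param series a [ContactMapSeries-class].
#' @param path cache file path.
#' @return `writeContactMaps` returns `path` invisibly; `readContactMaps`
#'   returns the [ContactMapSeries-class].
#' @export
writeContactMaps <- function(series, path) {
  stopifnot(is(series, "ContactMapSeries"))
  saveRDS(series, path, compress = "gzip")
  invisible(path)
}

#' @rdname writeContactMaps
#' @export
readContactMaps <- function(path) {
  obj <- readRDS(path)
  if (!is(obj, "ContactMapSeries"))
    stop("file does not contain a ContactMapSeries: ", path)
  obj
}
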