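# Seeded synthetic folding trajectories with ground-truth state labels.
#
# This is a statistical stand-in for real MD data, not a physical
# simulation: no force field, no integrator, no solvent. It produces the
# features the contact-map analysis relies on -- blocky near-diagonal
# helical contact patterns, gradual contact loss on unfolding, frame-to-
# frame positional jitter and metastable-state switching -- with known
# labels and a known native structure.

# Ideal C-alpha alpha-helix: rise 1.5 A/residue, ~100 deg twist, 2.3 A
# radius. Adjacent C-alpha distance ~3.8 A.
native_helix <- function(n, phase = 0) {
  i <- seq_len(n) - 1
  theta <- phase + i * 100 * pi / 180
  cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i)
}

# Beta-strand as a flat zigzag, ~3.5 A between consecutive C-alphas.
strand_zigzag <- function(n, origin = c(0, 0, 0), dir = c(1, 0, 0),
                          perp = c(0, 1, 0), step = 3.3, amp = 0.6) {
  i <- seq_len(n) - 1
  t(origin + outer(dir, i * step) + outer(perp, amp * (-1)^i))
}

# Beta-hairpin (two antiparallel strands + turn) packed against a C-terminal
# alpha-helix: a mixed beta-beta-alpha topology.
native_sheet_helix <- function(n) {
  n_helix <- max(6, round(n * 0.4))
  n_sheet <- n - n_helix
  n_s1 <- floor((n_sheet - 2) / 2)
  n_s2 <- n_sheet - 2 - n_s1
  s1 <- strand_zigzag(n_s1, origin = c(0, 0, 0))
  turn <- rbind(c(n_s1 * 3.3 + 1.5, 1.8, 0.5),
                c(n_s1 * 3.3 + 1.5, 3.6, -0.5))
  s2 <- strand_zigzag(n_s2, origin = c((n_s2 - 1) * 3.3, 4.8, 0),
                      dir = c(-1, 0, 0))
  hel <- native_helix(n_helix)
  # helix axis along x, packed 5.5 A above the sheet plane
  hel <- cbind(hel[, 3], hel[, 1] + 2.4, hel[, 2] + 5.5)
  rbind(s1, turn, s2, hel)
}

# Three-helix bundle (villin-like all-alpha topology).
native_bundle <- function(n) {
  n_loop <- 2
  n_hel <- n - 2 * n_loop
  n1 <- floor(n_hel / 3); n2 <- floor((n_hel - n1) / 2); n3 <- n_hel - n1 - n2
  h1 <- native_helix(n1)
  h2 <- native_helix(n2)
  h2 <- cbind(h2[, 1] + 8, h2[, 2], -h2[, 3] + 1.5 * n2)  # antiparallel
  h3 <- native_helix(n3)
  h3 <- cbind(h3[, 1] + 4, h3[, 2] + 7, h3[, 3])
  loop1 <- rbind(h1[n1, ] + c(2.5, 1.5, 1.5), h2[1, ] + c(-2.5, 1.5, 1.5))
  loop2 <- rbind(h2[n2, ] + c(-1.5, 2.5, -1.5), h3[1, ] + c(1.5, 2.5, -1.5))
  rbind(h1, loop1, h2, loop2, h3)
}

native_structure <- function(n, topology = c("helix", "sheet-helix",
                                             "bundle")) {
  topology <- match.arg(topology)
  switch(topology,
         "helix" = native_helix(n),
         "sheet-helix" = native_sheet_helix(n),
         "bundle" = native_bundle(n))
}

# Progressive unfolding: keep the first (1 - e) fraction of the chain
# native and extend the rest as a straight 3.8 A/residue tail pointing away
# from the folded body.
extend_chain <- function(native, e) {
  n <- nrow(native)
  keep <- max(2, n - round(e * n))
  if (keep >= n) return(native)
  out <- native
  body <- native[seq_len(keep), , drop = FALSE]
  dir <- native[keep, ] - colMeans(body)
  nd <- sqrt(sum(dir^2))
  dir <- if (nd < 1e-8) c(0, 0, 1) else dir / nd
  for (j in seq_len(n - keep))
    out[keep + j, ] <- native[keep, ] + 3.8 * j * dir
  out
}

rotation_about <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle)
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) * c_ + s_ * K + (1 - c_) * tcrossprod(a)
}

# Misfolded conformation: break the chain at the midpoint and rigidly
# repack the C-terminal segment antiparallel alongside the N-terminal one.
# Intra-segment native contacts survive (high Q); the repacked geometry is
# far from native (high RMSD) and gains a distinct off-diagonal contact
# block, so the state is visible to a contact-map model.
misfold_repack <- function(native, offset = 5.0) {
  n <- nrow(native)
  m <- floor(n / 2)
  t_end <- native[m, ] - native[m - 1, ]
  t_end <- t_end / sqrt(sum(t_end^2))
  p <- c(t_end[2] * 1 - t_end[3] * 0, t_end[3] * 0 - t_end[1] * 1,
         t_end[1] * 0 - t_end[2] * 0)           # t_end x (0, 0, 1)
  if (sum(p^2) < 1e-8) p <- c(1, 0, 0)
  p <- p / sqrt(sum(p^2))
  R <- rotation_about(p, pi)
  seg2 <- native[(m + 1):n, , drop = FALSE]
  rel <- sweep(seg2, 2, seg2[1, ])
  out <- native
  anchor <- native[m, ] + offset * p
  out[(m + 1):n, ] <- sweep(rel %*% t(R), 2, anchor, "+")
  out
}

#' Configuration for the synthetic folding-trajectory generator
#'
#' Each state is a deterministic deformation of the ideal native structure
#' targeting a fraction of native contacts `q` (unfolding by progressive
#' chain extension from the C-terminus), or -- for `misfolded = TRUE` -- a
#' two-segment repack that keeps most native contacts while sitting far
#' from the native structure. Frames evolve as a Markov chain over states:
#' with probability `switchProb` per frame the state is redrawn from the
#' occupancy weights (so the stationary occupancy equals the normalized
#' weights). Isotropic Gaussian jitter of `noiseSd` Angstrom is added per
#' atom and each frame receives a random global rotation + translation
#' (which the contact-map featurization must be blind to).
#'
#' @param nResidues chain length (default 21, an Fs-peptide-sized helix).
#' @param nFrames number of frames to generate.
#' @param states list of state specs `list(name=, q=, weight=,
#'   misfolded=)`. Default: folded (q 1.0), two partially folded
#'   (q 0.7, 0.4) and unfolded (q 0.1).
#' @param noiseSd per-atom positional jitter in Angstrom.
#' @param switchProb per-frame probability of redrawing the state.
#' @param seed integer seed; generation is bit-reproducible per seed.
#' @param topology native fold: `"helix"`, `"sheet-helix"` or `"bundle"`.
#' @return a validated configuration list.
#' @export
syntheticConfig <- function(nResidues = 21, nFrames = 1000,
                            states = NULL, noiseSd = 0.3,
                            switchProb = 0.02, seed = 1,
                            topology = "helix") {
  if (is.null(states))
    states <- list(
      list(name = "folded", q = 1.0, weight = 0.3, misfolded = FALSE),
      list(name = "partial1", q = 0.7, weight = 0.25, misfolded = FALSE),
      list(name = "partial2", q = 0.4, weight = 0.25, misfolded = FALSE),
      list(name = "unfolded", q = 0.1, weight = 0.2, misfolded = FALSE))
  if (length(states) < 1) stop("at least one state is required")
  states <- lapply(states, function(s) {
    if (is.null(s$misfolded)) s$misfolded <- FALSE
    if (!s$misfolded && (is.null(s$q) || s$q < 0 || s$q > 1))
      stop("state target q must lie in [0, 1]")
    if (is.null(s$weight) || s$weight <= 0)
      stop("state occupancy weights must be positive")
    s
  })
  if (switchProb < 0 || switchProb > 1)
    stop("switchProb must lie in [0, 1]")
  if (noiseSd < 0) stop("noiseSd must be nonnegative")
  if (nFrames < 0) stop("nFrames must be nonnegative")
  list(nResidues = as.integer(nResidues), nFrames = as.integer(nFrames),
       states = states, noiseSd = noiseSd, switchProb = switchProb,
       seed = as.integer(seed), topology = topology)
}

#' Generator presets mirroring the three study systems
#'
#' `"fs21"`: 21-residue single helix (Fs-peptide-sized);
#' `"bba28"`: 28-residue mixed beta-beta-alpha fold (BBA-sized);
#' `"vhp35"`: 35-residue three-helix bundle (villin-headpiece-sized).
#'
#' @param name preset name.
#' @param nFrames,seed passed through to [syntheticConfig()].
#' @param ... further overrides for [syntheticConfig()].
#' @return a configuration list.
#' @export
syntheticPreset <- function(name = c("fs21", "bba28", "vhp35"),
                            nFrames = 1000, seed = 1, ...) {
  name <- match.arg(name)
  preset_def <- switch(name,
                 fs21 = list(n = 21, topology = "helix"),
                 bba28 = list(n = 28, topology = "sheet-helix"),
                 vhp35 = list(n = 35, topology = "bundle"))
  syntheticConfig(nResidues = preset_def$n, nFrames = nFrames, seed = seed,
                  topology = preset_def$topology, ...)
}

# Q of a deformed conformation against the native contact set.
q_of <- function(coords, ref) {
  fractionNativeContacts(array(coords, c(1, dim(coords))), ref)
}

# Deterministic per-state conformations; stochasticity lives only in the
# jitter and the Markov chain.
state_conformations <- function(cfg, native, ref) {
  lapply(cfg$states, function(s) {
    if (isTRUE(s$misfolded))
      return(misfold_repack(native))
    es <- seq(0, 1, by = 0.02)
    qs <- vapply(es, function(e) q_of(extend_chain(native, e), ref),
                 numeric(1))
    best <- which.min(abs(qs - s$q))
    if (abs(qs[best] - s$q) > 0.2)
      stop("target q = ", s$q, " for state '", s$name,
           "' is not reachable with ", cfg$nResidues, " residues ",
           "(closest achievable: ", round(qs[best], 2), ")")
    extend_chain(native, es[best])
  })
}

random_rotation <- function() {
  M <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Generate a synthetic folding trajectory
#'
#' See [syntheticConfig()] for the generative model. The returned object
#' carries the frames, per-frame ground-truth state labels, the ideal
#' native structure and the configuration.
#'
#' @param cfg configuration from [syntheticConfig()] or [syntheticPreset()].
#' @return a [SyntheticTrajectory-class].
#' @examples
#' traj <- generateFoldingTrajectory(syntheticConfig(nFrames = 50, seed = 7))
#' table(stateLabels(traj))
#' @export
generateFoldingTrajectory <- function(cfg) {
  native <- native_structure(cfg$nResidues, cfg$topology)
  ref <- buildNativeReference(native)
  confs <- state_conformations(cfg, native, ref)
  names(confs) <- vapply(cfg$states, `[[`, character(1), "name")
  w <- vapply(cfg$states, `[[`, numeric(1), "weight")
  w <- w / sum(w)
  n <- cfg$nFrames
  N <- cfg$nResidues
  set.seed(cfg$seed)
  labels <- character(n)
  coords <- array(0, c(n, N, 3))
  if (n > 0) {
    s <- sample.int(length(w), 1, prob = w)
    for (f in seq_len(n)) {
      if (f > 1 && stats::runif(1) < cfg$switchProb)
        s <- sample.int(length(w), 1, prob = w)
      labels[f] <- names(confs)[s]
      x <- confs[[s]] +
        matrix(stats::rnorm(3 * N, sd = cfg$noiseSd), N, 3)
      x <- x %*% t(random_rotation())
      x <- sweep(x, 2, stats::runif(3, -20, 20), "+")
      coords[f, , ] <- x
    }
  }
  frames <- new("TrajectoryFrames", coords = coords, frameInterval = 1,
                sourceId = sprintf("synthetic-%s-%d", cfg$topology,
                                   cfg$seed))
  new("SyntheticTrajectory", frames = frames, labels = labels,
      native = native, config = cfg)
}

#' Generate two independent trajectories of the same system
#'
#' Both trajectories share the state repertoire and the native structure
#' and differ only in the stochastic realization (Markov chain, jitter,
#' rigid motions). Supports transfer experiments: train on A, project B.
#'
#' @param cfg configuration for the first trajectory.
#' @param seed2 seed for the second trajectory.
#' @return list of two [SyntheticTrajectory-class] objects.
#' @export
generatePairedTrajectories <- function(cfg, seed2) {
  cfg2 <- cfg
  cfg2$seed <- as.integer(seed2)
  list(generateFoldingTrajectory(cfg), generateFoldingTrajectory(cfg2))
}

#' Write a synthetic trajectory to disk
#'
#' Writes the native structure (PDB), the trajectory (multi-model PDB or
#' DCD, chosen by extension) and the ground-truth labels (CSV), so the
#' full file-reading path can be exercised end to end.
#'
#' @param traj a [SyntheticTrajectory-class].
#' @param dir output directory (created if needed).
#' @param trajFormat `"pdb"` or `"dcd"`.
#' @return named character vector of the written paths.
#' @export
writeSyntheticTrajectory <- function(traj, dir, trajFormat = c("pdb",
                                                               "dcd")) {
  trajFormat <- match.arg(trajFormat)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  native_path <- file.path(dir, "native.pdb")
  writeTrajectoryPDB(array(traj@native, c(1, dim(traj@native))), native_path)
  traj_path <- file.path(dir, paste0("traj.", trajFormat))
  if (trajFormat == "pdb") writeTrajectoryPDB(traj@frames, traj_path)
  else writeTrajectoryDCD(traj@frames, traj_path)
  labels_path <- file.path(dir, "labels.csv")
  utils::write.csv(data.frame(frame = seq_along(traj@labels),
                              state = traj@labels),
                   labels_path, row.names = FALSE)
  c(native = native_path, trajectory = traj_path, labels = labels_path)
}
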