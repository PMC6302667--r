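# Latent-space diagnostics: reconstruction differences, misprediction
# fraction, free-energy-surface histogram and state assignment.

#' Reconstruction difference maps
#'
#' Decodes each selected frame from its latent mean and subtracts the
#' original binary map, restricted to the unpadded `N x N` block. Values
#' lie in `[-1, 1]`: negative entries mispredict the presence of a contact,
#' positive entries its absence.
#'
#' @param model a trained [CVAEModel-class].
#' @param maps the [ContactMapSeries-class] the model was (or would be)
#'   applied to.
#' @param subset optional frame indices (default: all frames).
#' @param threshold misprediction tolerance stored with the result.
#' @return a [ReconstructionDiff-class].
#' @export
reconstructionDifference <- function(model, maps, subset = NULL,
                                     threshold = 0.1) {
  stopifnot(is(model, "CVAEModel"))
  if (model@trainedEpochs == 0)
    stop("model is untrained; train it before computing reconstruction ",
         "diagnostics")
  check_shape(model, maps)
  X <- maps_cube(maps)
  if (is.null(subset)) subset <- seq_len(dim(X)[3])
  if (length(subset) == 0) stop("subset is empty")
  N <- if (is(maps, "ContactMapSeries")) nResidues(maps) else dim(X)[1]
  X <- X[, , subset, drop = FALSE]
  emb <- encodeMaps(model, X, sample = FALSE)
  rec <- decodeLatent(model, emb@mu)
  diffs <- rec[seq_len(N), seq_len(N), , drop = FALSE] -
    X[seq_len(N), seq_len(N), , drop = FALSE]
  new("ReconstructionDiff", diffs = diffs, threshold = threshold)
}

#' Misprediction fraction
#'
#' Share of unpadded pixels whose reconstruction deviates from the true
#' binary value by strictly more than the threshold (default 0.1 on the
#' `[0, 1]` contact scale); the correct-contact fraction is its complement.
#' A pixel exactly at the threshold counts as correct.
#'
#' @param diff a [ReconstructionDiff-class].
#' @param threshold optional override of the stored threshold.
#' @return proportion in `[0, 1]`.
#' @export
mispredictionFraction <- function(diff, threshold = NULL) {
  stopifnot(is(diff, "ReconstructionDiff"))
  thr <- if (is.null(threshold)) diff@threshold else threshold
  if (thr <= 0 || thr >= 1) stop("threshold must lie in (0, 1)")
  mean(abs(diff@diffs) > thr)
}

#' Free-energy-surface histogram
#'
#' Bins the 2-D projected coordinates and returns
#' `F(bin) = -log(count / max count)` for occupied bins, a simple
#' qualitative estimate of the free-energy landscape: 0 at the modal bin,
#' increasing with decreasing occupancy, `NA` where empty.
#'
#' @param xy numeric `frames x 2` matrix (e.g. from [tsneProject()]).
#' @param bins number of bins per axis (>= 2).
#' @return a `bins x bins` matrix with attributes `xbreaks` and `ybreaks`.
#' @export
fesHistogram <- function(xy, bins = 64) {
  xy <- as.matrix(xy)
  stopifnot(ncol(xy) == 2, bins >= 2)
  pad_range <- function(v) {
    r <- range(v)
    if (r[1] == r[2]) r <- r + c(-0.5, 0.5)
    r
  }
  xb <- seq(pad_range(xy[, 1])[1], pad_range(xy[, 1])[2], length.out = bins + 1)
  yb <- seq(pad_range(xy[, 2])[1], pad_range(xy[, 2])[2], length.out = bins + 1)
  xi <- pmin(pmax(findInterval(xy[, 1], xb, rightmost.closed = TRUE), 1), bins)
  yi <- pmin(pmax(findInterval(xy[, 2], yb, rightmost.closed = TRUE), 1), bins)
  counts <- matrix(0, bins, bins)
  for (i in seq_len(nrow(xy)))
    counts[xi[i], yi[i]] <- counts[xi[i], yi[i]] + 1
  fes <- matrix(NA_real_, bins, bins)
  occ <- counts > 0
  fes[occ] <- -log(counts[occ] / max(counts))
  attr(fes, "xbreaks") <- xb
  attr(fes, "ybreaks") <- yb
  attr(fes, "counts") <- counts
  fes
}

#' Assign conformational states by seeded k-means
#'
#' Clusters frames (on t-SNE coordinates or latent means) into k states and
#' summarizes each state with its population and, when reaction coordinates
#' are supplied, mean RMSD and mean Q. A state is flagged as a
#' misfolded candidate when it keeps a high fraction of native contacts
#' (`mean Q >= qHi`) while sitting far from the native structure
#' (`mean RMSD >= rHi`) -- both conditions simultaneously.
#'
#' @param xy numeric `frames x p` coordinate matrix (t-SNE output or latent
#'   `mu`).
#' @param k number of states (>= 1).
#' @param seed integer seed for k-means initialization.
#' @param rmsd,q optional per-frame reaction coordinates for the summaries.
#' @param qHi,rHi thresholds for the misfolded-candidate flag. `rHi` is
#'   system-specific (set it to the RMSD that separates folded from
#'   non-folded for your protein); the flag stays `NA` when `rHi` is `NULL`
#'   or coordinates are missing.
#' @return list with `labels` (integer vector in `1..k`) and `summary`
#'   (one row per state: population, meanRmsd, meanQ, misfoldedCandidate).
#' @export
assignStates <- function(xy, k, seed = 1, rmsd = NULL, q = NULL,
                         qHi = 0.8, rHi = NULL) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (k < 1) stop("k must be >= 1")
  if (k > n) stop("k = ", k, " exceeds the number of frames (", n, ")")
  if (k == 1) {
    labels <- rep(1L, n)
  } else {
    set.seed(seed)
    labels <- stats::kmeans(xy, centers = k, nstart = 10,
                            iter.max = 100)$cluster
  }
  summ <- data.frame(state = seq_len(k),
                     population = as.integer(tabulate(labels, k)))
  summ$meanRmsd <- if (is.null(rmsd)) NA_real_ else
    vapply(seq_len(k), function(s) mean(rmsd[labels == s]), numeric(1))
  summ$meanQ <- if (is.null(q)) NA_real_ else
    vapply(seq_len(k), function(s) mean(q[labels == s]), numeric(1))
  summ$misfoldedCandidate <-
    if (is.null(rmsd) || is.null(q) || is.null(rHi)) NA else
      summ$meanQ >= qHi & summ$meanRmsd >= rHi
  list(labels = labels, summary = summ)
}

#' Write per-frame embeddings and coordinates to CSV
#'
#' @param embedding a [LatentEmbedding-class].
#' @param path output CSV path.
#' @param tsne optional `frames x 2` t-SNE coordinates.
#' @param states optional per-frame state labels.
#' @param rmsd,q optional per-frame reaction coordinates.
#' @return `path`, invisibly.
#' @export
writeEmbeddings <- function(embedding, path, tsne = NULL, states = NULL,
                            rmsd = NULL, q = NULL) {
  mu <- latentMu(embedding)
  df <- data.frame(frame = seq_len(nrow(mu)))
  for (j in seq_len(ncol(mu))) df[[paste0("z", j)]] <- mu[, j]
  if (!is.null(tsne)) { df$tsne1 <- tsne[, 1]; df$tsne2 <- tsne[, 2] }
  if (!is.null(states)) df$state <- states
  if (!is.null(rmsd)) df$rmsd_A <- rmsd
  if (!is.null(q)) df$q_native <- q
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Render a free-energy-surface histogram to PNG
#'
#' @param fes output of [fesHistogram()].
#' @param path output PNG path.
#' @param main plot title.
#' @return `path`, invisibly.
#' @export
plotLandscape <- function(fes, path, main = "-log histogram landscape") {
  grDevices::png(path, width = 800, height = 700)
  on.exit(grDevices::dev.off())
  xb <- attr(fes, "xbreaks"); yb <- attr(fes, "ybreaks")
  graphics::image(x = xb, y = yb, z = fes,
                  col = grDevices::hcl.colors(64, "viridis", rev = TRUE),
                  xlab = "t-SNE 1", ylab = "t-SNE 2", main = main,
                  useRaster = TRUE)
  invisible(path)
}
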