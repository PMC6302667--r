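# Exact (dense) t-SNE. O(n^2) memory and time per iteration, which is fine
# at the few-thousand-frame scale the latent diagnostics run at; larger
# trajectories should be subsampled first.

# Conditional Gaussian similarities with per-point bandwidths found by
# bisection on the Shannon perplexity.
tsne_p_matrix <- function(X, perplexity) {
  n <- nrow(X)
  D2 <- as.matrix(stats::dist(X))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    beta <- 1
    lo <- -Inf; hi <- Inf
    for (iter in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw < 1e-300) { H <- 0 } else {
        H <- log(sw) + beta * sum(di * w) / sw
      }
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2
                                          else beta * 2 }
      else          { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2
                                          else beta / 2 }
    }
    w <- exp(-di * beta)
    sw <- sum(w)
    P[i, -i] <- if (sw < 1e-300) 1 / (n - 1) else w / sw
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

#' Project latent embeddings to 2-D with t-SNE
#'
#' Exact t-distributed stochastic neighbour embedding of the latent means
#' (sampled `z` would add stochastic jitter the projection should not
#' reflect). Standard settings: early exaggeration 12 for the first quarter
#' of the iterations, learning rate 200, momentum 0.5 rising to 0.8.
#' Deterministic for a fixed seed.
#'
#' @param embedding a [LatentEmbedding-class] (its `mu` is used) or a
#'   numeric `frames x d` matrix.
#' @param perplexity target perplexity; requires `frames > 3 * perplexity`.
#' @param seed integer seed for the initial layout.
#' @param maxIter number of gradient iterations.
#' @return numeric `frames x 2` matrix of projected coordinates.
#' @export
tsneProject <- function(embedding, perplexity = 30, seed = 1,
                        maxIter = 500) {
  X <- if (is(embedding, "LatentEmbedding")) embedding@mu
       else as.matrix(embedding)
  n <- nrow(X)
  if (n <= 3 * perplexity)
    stop("too few frames (", n, ") for perplexity ", perplexity,
         "; need frames > 3 * perplexity")
  P <- tsne_p_matrix(X, perplexity)
  set.seed(seed)
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  G <- matrix(0, n, 2)     # momentum accumulator
  gains <- matrix(1, n, 2)
  exag_iters <- max(50, round(maxIter / 4))
  for (it in seq_len(maxIter)) {
    Pe <- if (it <= exag_iters) P * 12 else P
    num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    W <- (Pe - Q) * num
    grad <- 4 * (Y * rowSums(W) - W %*% Y)
    mom <- if (it <= 250) 0.5 else 0.8
    gains <- ifelse(sign(grad) != sign(G), gains + 0.2, gains * 0.8)
    gains <- pmax(gains, 0.01)
    G <- mom * G - 200 * gains * grad
    Y <- Y + G
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}
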