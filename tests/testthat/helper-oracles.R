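# Independent oracles and small utilities shared across the test files.

# O(N^2) brute-force contact map: the reference the fast path must equal.
brute_contact_map <- function(coords, cutoff = 8) {
  n <- nrow(coords)
  m <- matrix(0, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      m[i, j] <- as.numeric(sqrt(sum((coords[i, ] - coords[j, ])^2)) < cutoff)
  m
}

random_rotation_matrix <- function() {
  M <- matrix(rnorm(9), 3, 3)
  d <- qr(M)
  Q <- qr.Q(d) %*% diag(sign(diag(qr.R(d))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

euler_rotation <- function(a, b, c) {
  Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1),
                           3, 3)
  Ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)),
                           3, 3)
  Rz(a) %*% Ry(b) %*% Rz(c)
}

# Brute-force minimal RMSD: coarse grid over Euler angles followed by
# Nelder-Mead refinement from the best grid point. Independent of the
# SVD-based implementation under test.
rmsd_rotation_oracle <- function(A, B) {
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  obj <- function(ang) {
    R <- euler_rotation(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((A %*% t(R) - B)^2)))
  }
  grid <- expand.grid(a = seq(0, 2 * pi, length.out = 13)[-13],
                      b = seq(0, pi, length.out = 7),
                      c = seq(0, 2 * pi, length.out = 13)[-13])
  vals <- apply(grid, 1, obj)
  best <- as.numeric(grid[which.min(vals), ])
  opt <- stats::optim(best, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  opt$value
}

# Scalar-loop binary cross entropy, independent of the C++ implementation.
bce_loop_oracle <- function(X, F) {
  tot <- 0
  n <- dim(X)[3]
  for (s in seq_len(n))
    for (i in seq_len(dim(X)[1]))
      for (j in seq_len(dim(X)[2])) {
        f <- min(max(F[i, j, s], 1e-7), 1 - 1e-7)
        tot <- tot - (X[i, j, s] * log(f) + (1 - X[i, j, s]) * log(1 - f))
      }
  tot / n
}

kl_loop_oracle <- function(mu, lv) {
  tot <- 0
  for (i in seq_len(nrow(mu)))
    for (j in seq_len(ncol(mu)))
      tot <- tot - 0.5 * (1 + lv[i, j] - mu[i, j]^2 - exp(lv[i, j]))
  tot / nrow(mu)
}

# Cluster purity against ground-truth labels.
purity <- function(cluster, truth) {
  sum(apply(table(cluster, truth), 1, max)) / length(truth)
}

# Ideal helical native structure (same geometry the generator uses).
native_coords_for_tests <- function(n) foldcvae:::native_helix(n)

# frames x N x 3 array from a list of N x 3 matrices
frames_array <- function(...) {
  xs <- list(...)
  out <- array(0, c(length(xs), nrow(xs[[1]]), 3))
  for (i in seq_along(xs)) out[i, , ] <- xs[[i]]
  out
}
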