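# CVAE: hyperparameters, losses, training contracts, encode/decode,
# search and transfer.

tiny_hp <- function(...) {
  args <- list(nConvLayers = 2, nFilters = 16, kernel = 3, nDense = 32,
               latentDim = 3)
  do.call(cvaeHyperparams, utils::modifyList(args, list(...)))
}

tiny_maps <- function(n = 40, seed = 31) {
  traj <- generateFoldingTrajectory(syntheticConfig(nFrames = n, seed = seed))
  padMaps(computeContactMaps(traj@frames))
}

test_that("hyperparameter bounds are enforced", {
  expect_error(cvaeHyperparams(nConvLayers = 5), "outside bounds")
  expect_error(cvaeHyperparams(nFilters = 10), "outside bounds")
  expect_error(cvaeHyperparams(latentDim = 1), "outside bounds")
  expect_error(cvaeHyperparams(optimizer = "sgd"), "optimizer")
  # lower-bound latent width is a valid model
  m <- buildModel(tiny_hp(latentDim = 2), 24)
  expect_equal(latentDim(m), 2)
})

test_that("models report shape requirements", {
  expect_error(buildModel(tiny_hp(), 21), "even")
  m <- buildModel(tiny_hp(), 24)
  expect_error(encodeMaps(m, array(0, c(28, 28, 2))), "input size")
})

test_that("reconstruction loss matches its closed forms and a scalar-loop
           oracle", {
  # perfect reconstruction (clipped): loss below 1e-5 per pixel
  X <- contactMaps(tiny_maps(5))
  expect_lt(reconstructionLoss(X, X) / prod(dim(X)[1:2]), 1e-5)
  # single pixel X = 1, f = 0.5 contributes ln 2
  expect_equal(reconstructionLoss(matrix(1, 1, 1), matrix(0.5, 1, 1)),
               log(2), tolerance = 1e-9)
  set.seed(33)
  for (rep in 1:10) {
    Xr <- array(rbinom(2 * 6 * 6, 1, 0.5), c(6, 6, 2))
    Fr <- array(runif(2 * 6 * 6), c(6, 6, 2))
    expect_equal(reconstructionLoss(Xr, Fr), bce_loop_oracle(Xr, Fr),
                 tolerance = 1e-6)
  }
  expect_error(reconstructionLoss(array(0, c(2, 2, 1)),
                                  array(0.5, c(3, 3, 1))), "mismatch")
})

test_that("latent loss has its closed-form values and is nonnegative", {
  expect_equal(latentLoss(0, 0), 0)
  expect_equal(latentLoss(1, 0), 0.5)            # d = 1, mu = 1, sigma = 1
  set.seed(34)
  mu <- matrix(rnorm(1000 * 2, sd = 2), 1000)
  lv <- matrix(rnorm(1000 * 2, sd = 2), 1000)
  expect_gte(min(vapply(1:1000, function(i)
    latentLoss(mu[i, , drop = FALSE], lv[i, , drop = FALSE]),
    numeric(1))), 0)
  expect_equal(latentLoss(mu, lv), kl_loop_oracle(mu, lv),
               tolerance = 1e-9)
})

test_that("analytic gradients match numerical differentiation", {
  hp <- list(input_dim = 8L, n_conv_layers = 2L, n_filters = 3L,
             kernel = 3L, n_dense = 7L, latent_dim = 2L)
  set.seed(35)
  W <- foldcvae:::cvae_init_cpp(hp, 42L)
  # jitter away from ReLU kinks at exactly zero
  W <- lapply(W, function(m) m + matrix(rnorm(length(m), 0, 0.01), nrow(m)))
  X <- matrix(rbinom(64, 1, 0.4), 8, 8)
  X <- 1 * ((X + t(X)) > 0); diag(X) <- 1
  eps <- matrix(rnorm(2), 1)
  r <- foldcvae:::cvae_loss_grad_cpp(W, hp, X, eps)
  h <- 1e-5
  for (pi in seq_along(W)) {
    for (j in sample(length(W[[pi]]), min(3, length(W[[pi]])))) {
      Wp <- W; Wp[[pi]][j] <- Wp[[pi]][j] + h
      Wn <- W; Wn[[pi]][j] <- Wn[[pi]][j] - h
      num <- (foldcvae:::cvae_loss_grad_cpp(Wp, hp, X, eps)$loss -
              foldcvae:::cvae_loss_grad_cpp(Wn, hp, X, eps)$loss) / (2 * h)
      expect_equal(r$grads[[pi]][j], num, tolerance = 1e-4)
    }
  }
})

test_that("zero-epoch training is a no-op with an empty trace", {
  maps <- tiny_maps()
  m <- buildModel(tiny_hp(), mapSize(maps), seed = 3)
  m2 <- trainModel(m, maps, splitDataset(nFrames(maps)), epochs = 0)
  expect_identical(m2@weights, m@weights)
  expect_equal(nrow(lossTrace(m2)), 0)
})

test_that("training is bit-reproducible for a fixed seed and satisfies
           L = E_r + E_l", {
  maps <- tiny_maps()
  sp <- splitDataset(nFrames(maps))
  m <- buildModel(tiny_hp(), mapSize(maps), seed = 3)
  a <- trainModel(m, maps, sp, seed = 9, epochs = 3)
  b <- trainModel(m, maps, sp, seed = 9, epochs = 3)
  expect_identical(lossTrace(a), lossTrace(b))
  expect_identical(a@weights, b@weights)
  tr <- lossTrace(a)
  expect_lt(max(abs(tr$train_L - (tr$train_Er + tr$train_El)) /
                  tr$train_L), 1e-6)
  expect_lt(max(abs(tr$val_L - (tr$val_Er + tr$val_El)) / tr$val_L), 1e-6)
  c_ <- trainModel(m, maps, sp, seed = 10, epochs = 3)
  expect_false(identical(lossTrace(a)$train_L, lossTrace(c_)$train_L))
})

test_that("every supported optimizer reduces the training loss", {
  maps <- tiny_maps(60)
  sp <- splitDataset(nFrames(maps))
  for (opt in c("rmsprop", "adam", "adamax", "adagrad")) {
    m <- buildModel(tiny_hp(optimizer = opt), mapSize(maps), seed = 3)
    m <- trainModel(m, maps, sp, seed = 9, epochs = 5)
    tr <- lossTrace(m)
    expect_lt(tr$train_L[nrow(tr)], tr$train_L[1])
  }
})

test_that("encode gives identical mu for duplicated frames; decode stays
           strictly inside (0, 1)", {
  maps <- tiny_maps(10)
  m <- buildModel(tiny_hp(), mapSize(maps), seed = 3)
  X <- contactMaps(maps)
  dup <- array(c(X[, , 1], X[, , 1]), c(24, 24, 2))
  emb <- encodeMaps(m, dup)
  expect_identical(latentMu(emb)[1, ], latentMu(emb)[2, ])
  set.seed(36)
  dec <- decodeLatent(m, matrix(rnorm(5 * 3, sd = 2), 5, 3))
  expect_gt(min(dec), 0)
  expect_lt(max(dec), 1)
  # sampling is seeded and optional
  e1 <- encodeMaps(m, dup, seed = 5)
  e2 <- encodeMaps(m, dup, seed = 5)
  expect_identical(latentZ(e1), latentZ(e2))
  expect_false(identical(latentZ(e1), latentMu(e1)))
  e3 <- encodeMaps(m, dup, sample = FALSE)
  expect_identical(latentZ(e3), latentMu(e3))
})

test_that("hyperparameter search handles degenerate spaces, is seeded, and
           ranks by validation loss", {
  maps <- tiny_maps(50)
  sp <- splitDataset(nFrames(maps))
  point <- list(nConvLayers = c(1, 1), nFilters = c(16, 16),
                kernel = c(3, 3), nDense = c(32, 32), latentDim = c(3, 3))
  res <- hyperparameterSearch(maps, sp, bounds = point, budget = 1,
                              epochs = 1, seed = 5)
  expect_equal(nrow(res), 1)
  expect_equal(res$nFilters, 16)

  r1 <- hyperparameterSearch(maps, sp, budget = 3, epochs = 1, seed = 8)
  r2 <- hyperparameterSearch(maps, sp, budget = 3, epochs = 1, seed = 8)
  expect_identical(r1, r2)
  expect_true(!is.unsorted(r1$val_Er))
})

test_that("transfer on the training maps reproduces the original embedding
           and rejects mismatched shapes", {
  fix <- small_trained_fixture()
  res <- transferProject(fix$model, fix$maps, seed = 4)
  emb <- encodeMaps(fix$model, fix$maps, seed = 4)
  expect_identical(latentMu(res$embedding), latentMu(emb))
  wrong <- array(0, c(28, 28, 3))
  expect_error(transferProject(fix$model, wrong), "input size")
})
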