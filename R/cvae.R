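# Convolutional variational autoencoder: hyperparameters, model building,
# losses, training, encoding/decoding, hyperparameter search and transfer.

# Search-space bounds for each tunable hyperparameter.
HP_BOUNDS <- list(
  nConvLayers = c(1L, 4L),
  nFilters    = c(16L, 125L),
  kernel      = c(2L, 7L),
  nDense      = c(32L, 100L),
  latentDim   = c(2L, 16L)
)

OPTIMIZERS <- c("rmsprop", "adam", "adamax", "adagrad")

#' CVAE hyperparameters
#'
#' Validated hyperparameter set for [buildModel()]. Bounds follow the
#' tuning box used for the architecture: 1-4 convolutional layers, 16-125
#' filters, kernels 2x2 to 7x7, 32-100 dense units and a latent width of
#' 2-16. The default optimizer is RMSprop, which reconstructs held-out
#' contact maps best among the four supported optimizers in our experiments.
#'
#' @param nConvLayers number of convolutional layers in the encoder (the
#'   decoder mirrors them).
#' @param nFilters filters per convolutional layer.
#' @param kernel square kernel side m.
#' @param nDense width of the fully connected layer.
#' @param latentDim latent dimensionality d (>= 2).
#' @param optimizer one of `"rmsprop"`, `"adam"`, `"adamax"`, `"adagrad"`.
#' @param epochs default training epoch budget.
#' @param learningRate optimizer learning rate.
#' @return a named list of class `"cvaeHyperparams"`.
#' @examples
#' cvaeHyperparams(latentDim = 3)
#' @export
cvaeHyperparams <- function(nConvLayers = 4, nFilters = 100, kernel = 5,
                            nDense = 64, latentDim = 3,
                            optimizer = "rmsprop", epochs = 150,
                            learningRate = 1e-3) {
  hp <- list(nConvLayers = as.integer(nConvLayers),
             nFilters = as.integer(nFilters),
             kernel = as.integer(kernel),
             nDense = as.integer(nDense),
             latentDim = as.integer(latentDim),
             optimizer = tolower(optimizer),
             epochs = as.integer(epochs),
             learningRate = as.numeric(learningRate))
  for (nm in names(HP_BOUNDS)) {
    b <- HP_BOUNDS[[nm]]
    if (hp[[nm]] < b[1] || hp[[nm]] > b[2])
      stop(nm, " = ", hp[[nm]], " outside bounds [", b[1], ", ", b[2], "]")
  }
  if (!hp$optimizer %in% OPTIMIZERS)
    stop("optimizer must be one of: ", paste(OPTIMIZERS, collapse = ", "))
  if (hp$epochs < 0) stop("epochs must be >= 0")
  if (hp$learningRate <= 0) stop("learningRate must be positive")
  class(hp) <- "cvaeHyperparams"
  hp
}

# hyperparameter list in the form the C++ core expects
hp_cpp <- function(hp, inputDim) {
  list(input_dim = as.integer(inputDim),
       n_conv_layers = hp$nConvLayers, n_filters = hp$nFilters,
       kernel = hp$kernel, n_dense = hp$nDense, latent_dim = hp$latentDim)
}

#' Build an (untrained) CVAE
#'
#' Encoder: `nConvLayers` stride-1 same-padded convolutions (ReLU) followed
#' by a single 2x2 stride-2 mean-pool, a dense ReLU layer and linear
#' `(mu, log sigma^2)` heads of width `latentDim`. The decoder mirrors the
#' encoder and ends in a per-pixel sigmoid, so reconstructions are contact
#' probabilities strictly inside (0, 1). Weights are Glorot-initialized from
#' the given seed.
#'
#' @param hp hyperparameters from [cvaeHyperparams()].
#' @param inputDim square input side M (even; use [padMaps()] to reach it).
#' @param seed integer seed for weight initialization.
#' @return an untrained [CVAEModel-class].
#' @examples
#' m <- buildModel(cvaeHyperparams(nConvLayers = 2, nFilters = 16, kernel = 3),
#'                 inputDim = 24)
#' @export
buildModel <- function(hp, inputDim, seed = 1) {
  stopifnot(inherits(hp, "cvaeHyperparams"))
  inputDim <- as.integer(inputDim)
  if (inputDim < 2 || inputDim %% 2 != 0)
    stop("inputDim must be an even integer >= 2; the smallest compatible ",
         "size for this input is ", defaultPaddedSize(inputDim))
  weights <- cvae_init_cpp(hp_cpp(hp, inputDim), as.integer(seed))
  new("CVAEModel", hyperparams = unclass(hp), weights = weights,
      inputDim = inputDim, trainedEpochs = 0L,
      lossTrace = empty_trace())
}

empty_trace <- function() {
  data.frame(epoch = integer(), train_L = numeric(), train_Er = numeric(),
             train_El = numeric(), val_L = numeric(), val_Er = numeric(),
             val_El = numeric())
}

maps_cube <- function(maps) {
  if (is(maps, "ContactMapSeries")) maps@maps else maps
}

check_shape <- function(model, maps) {
  M <- dim(maps_cube(maps))[1]
  if (M != model@inputDim)
    stop("map size ", M, " does not match the model input size ",
         model@inputDim, "; pad the maps to ", model@inputDim, "x",
         model@inputDim)
}

#' Reconstruction loss (binary cross entropy)
#'
#' Mean over the batch of the per-map summed binary cross entropy
#' `-sum(X log f + (1 - X) log(1 - f))` between the original binary contact
#' maps `X` and the reconstructed contact probabilities `f`, which are
#' clipped to `[1e-7, 1 - 1e-7]` before the logs.
#'
#' @param X original maps: an `M x M` matrix or `M x M x n` array (or
#'   [ContactMapSeries-class]).
#' @param fz reconstructions of the same shape with entries in (0, 1).
#' @return nonnegative scalar.
#' @examples
#' reconstructionLoss(matrix(1, 1, 1), matrix(0.5, 1, 1))  # log(2)
#' @export
reconstructionLoss <- function(X, fz) {
  X <- maps_cube(X); fz <- maps_cube(fz)
  if (is.matrix(X)) X <- array(X, c(dim(X), 1))
  if (is.matrix(fz)) fz <- array(fz, c(dim(fz), 1))
  if (!all(dim(X) == dim(fz)))
    stop("shape mismatch between maps and reconstructions")
  cvae_bce_cpp(X, fz)
}

#' Latent loss (KL divergence to the standard normal)
#'
#' Mean over the batch of the closed-form
#' `KL(N(mu, sigma^2) || N(0, 1)) = -1/2 sum_j (1 + log sigma_j^2 - mu_j^2
#' - sigma_j^2)`. Zero iff `mu = 0` and `logVar = 0`; nonnegative always.
#'
#' @param mu,logVar numeric `batch x d` matrices (or vectors).
#' @return nonnegative scalar.
#' @examples
#' latentLoss(0, 0)   # 0
#' latentLoss(1, 0)   # 0.5
#' @export
latentLoss <- function(mu, logVar) {
  if (!is.matrix(mu)) mu <- matrix(mu, nrow = 1)
  if (!is.matrix(logVar))
    logVar <- matrix(logVar, nrow = nrow(mu), ncol = ncol(mu))
  if (!all(is.finite(mu)) || !all(is.finite(logVar)))
    stop("mu and logVar must be finite")
  cvae_kl_cpp(mu, logVar)
}

#' Train a CVAE
#'
#' Minimizes `L = E_r + E_l` (reconstruction cross entropy plus KL latent
#' loss, see [reconstructionLoss()] and [latentLoss()]) by minibatch
#' gradient descent with the configured optimizer. The batch size defaults
#' to `ceiling(|train| / 100)` -- kept deliberately small so the latent
#' space does not collapse. Sampling uses the reparameterization
#' `z = mu + exp(logVar/2) * eps` during training; validation losses are
#' evaluated with deterministic `z = mu`. Fully reproducible for a fixed
#' seed.
#'
#' @param model a [CVAEModel-class] from [buildModel()].
#' @param maps a padded [ContactMapSeries-class] matching the model input.
#' @param split a [DatasetSplit-class] over the frames of `maps`.
#' @param seed integer seed for shuffling and latent sampling.
#' @param epochs number of epochs (default: the hyperparameter setting).
#' @param batchSize minibatch size (default `ceiling(|train|/100)`).
#' @param patience if > 0, stop early when the validation loss has not
#'   improved by more than `tol` for `patience` consecutive epochs.
#' @param tol minimum validation-loss improvement for early stopping.
#' @return the trained [CVAEModel-class] with an appended loss trace.
#' @export
trainModel <- function(model, maps, split, seed = 1, epochs = NULL,
                       batchSize = NULL, patience = 0, tol = 1e-3) {
  stopifnot(is(model, "CVAEModel"), is(split, "DatasetSplit"))
  check_shape(model, maps)
  X <- maps_cube(maps)
  n <- dim(X)[3]
  if (max(c(split@trainIdx, split@testIdx, split@valIdx)) > n)
    stop("split indices exceed the number of frames")
  if (length(split@trainIdx) == 0)
    stop("empty training set")
  if (is.null(epochs)) epochs <- model@hyperparams$epochs
  if (epochs == 0)
    return(model)
  if (is.null(batchSize)) batchSize <- ceiling(length(split@trainIdx) / 100)
  hp <- model@hyperparams
  fit <- cvae_train_cpp(model@weights, hp_cpp(hp, model@inputDim), X,
                        split@trainIdx - 1L, split@valIdx - 1L,
                        as.integer(epochs), as.integer(batchSize),
                        hp$optimizer, hp$learningRate, as.integer(seed),
                        as.integer(patience), tol)
  tr <- as.data.frame(fit$trace)
  names(tr) <- names(empty_trace())
  tr$epoch <- tr$epoch + model@trainedEpochs
  model@weights <- fit$weights
  model@lossTrace <- rbind(model@lossTrace, tr)
  model@trainedEpochs <- model@trainedEpochs + as.integer(nrow(tr))
  model
}

#' Encode contact maps into the latent space
#'
#' Runs the encoder on every frame and returns the per-frame posterior mean
#' `mu`, log-variance and one reparameterized sample `z`. `mu` is
#' deterministic; only `z` depends on the seed.
#'
#' @param model a [CVAEModel-class].
#' @param maps a [ContactMapSeries-class] (or array) matching the model
#'   input size.
#' @param seed integer seed for the latent sample.
#' @param sample if `FALSE`, `z = mu` (no sampling).
#' @return a [LatentEmbedding-class].
#' @export
encodeMaps <- function(model, maps, seed = 1, sample = TRUE) {
  stopifnot(is(model, "CVAEModel"))
  check_shape(model, maps)
  enc <- cvae_encode_cpp(model@weights, hp_cpp(model@hyperparams,
                                               model@inputDim),
                         maps_cube(maps), as.integer(seed), sample)
  new("LatentEmbedding", mu = enc$mu, logVar = enc$log_var, z = enc$z)
}

#' Decode latent coordinates into contact probabilities
#'
#' @param model a [CVAEModel-class].
#' @param z numeric `frames x d` matrix of latent coordinates.
#' @return `M x M x frames` array of contact probabilities strictly inside
#'   (0, 1).
#' @export
decodeLatent <- function(model, z) {
  stopifnot(is(model, "CVAEModel"))
  z <- if (is.matrix(z)) z else matrix(z, nrow = 1)
  if (ncol(z) != model@hyperparams$latentDim)
    stop("z has ", ncol(z), " columns; model latent dimension is ",
         model@hyperparams$latentDim)
  cvae_decode_cpp(model@weights, hp_cpp(model@hyperparams, model@inputDim), z)
}

#' Search the hyperparameter space
#'
#' Trains one reduced-epoch model per evaluation and ranks configurations
#' by validation reconstruction loss. `"random"` samples uniformly from the
#' bounds box; `"bayesian"` fits a Gaussian-process surrogate (RBF kernel on
#' the scaled box) and picks each next configuration by expected
#' improvement after `min(4, budget)` seeding evaluations.
#'
#' @param maps a padded [ContactMapSeries-class].
#' @param split a [DatasetSplit-class].
#' @param bounds named list of `c(lower, upper)` integer bounds; defaults to
#'   the standard tuning box (see [cvaeHyperparams()]).
#' @param budget number of configurations to evaluate.
#' @param strategy `"random"` or `"bayesian"`.
#' @param seed integer seed.
#' @param epochs training epochs per evaluation.
#' @param optimizer,learningRate fixed training settings per evaluation.
#' @param maxSeconds soft wall-clock cap; when exceeded the search returns
#'   the evaluations done so far with a warning.
#' @return data.frame of evaluated configurations with their validation
#'   reconstruction losses, ordered best first.
#' @export
hyperparameterSearch <- function(maps, split, bounds = HP_BOUNDS, budget = 8,
                                 strategy = c("random", "bayesian"), seed = 1,
                                 epochs = 5, optimizer = "rmsprop",
                                 learningRate = 1e-3, maxSeconds = Inf) {
  strategy <- match.arg(strategy)
  stopifnot(budget >= 1)
  M <- mapSize(maps)
  lower <- vapply(bounds, `[`, numeric(1), 1)
  upper <- vapply(bounds, `[`, numeric(1), 2)
  nm <- names(bounds)
  set.seed(seed)
  sample_config <- function() {
    round(lower + stats::runif(length(lower)) * (upper - lower))
  }
  evaluate <- function(x) {
    hp <- cvaeHyperparams(nConvLayers = x["nConvLayers"],
                          nFilters = x["nFilters"], kernel = x["kernel"],
                          nDense = x["nDense"], latentDim = x["latentDim"],
                          optimizer = optimizer, epochs = epochs,
                          learningRate = learningRate)
    m <- buildModel(hp, M, seed = seed)
    m <- trainModel(m, maps, split, seed = seed, epochs = epochs)
    tr <- m@lossTrace
    tr$val_Er[nrow(tr)]
  }
  X <- matrix(NA_real_, 0, length(lower), dimnames = list(NULL, nm))
  y <- numeric(0)
  t0 <- Sys.time()
  for (i in seq_len(budget)) {
    if (as.numeric(Sys.time() - t0, units = "secs") > maxSeconds) {
      warning("wall-clock cap reached after ", i - 1,
              " evaluations; returning partial results")
      break
    }
    if (strategy == "random" || i <= min(4, budget) || all(upper == lower)) {
      x <- sample_config()
    } else {
      x <- gp_ei_propose(X, y, lower, upper, n_cand = 256)
    }
    names(x) <- nm
    X <- rbind(X, x)
    y <- c(y, evaluate(x))
  }
  out <- as.data.frame(X)
  out$val_Er <- y
  rownames(out) <- NULL
  out[order(out$val_Er), ]
}

# Gaussian-process expected-improvement proposal on the scaled unit box
# (RBF kernel, fixed lengthscale 0.3, jitter 1e-8). Deliberately compact:
# the search spaces here are small integer boxes.
gp_ei_propose <- function(X, y, lower, upper, n_cand = 256) {
  scale01 <- function(m) sweep(sweep(m, 2, lower), 2,
                               pmax(upper - lower, 1), "/")
  Xs <- scale01(X)
  mu_y <- mean(y); sd_y <- max(stats::sd(y), 1e-12)
  ys <- (y - mu_y) / sd_y
  k <- function(A, B) {
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
    exp(-pmax(d2, 0) / (2 * 0.3^2))
  }
  K <- k(Xs, Xs) + diag(1e-6, nrow(Xs))
  Ki <- solve(K)
  cand <- t(replicate(n_cand,
                      round(lower + stats::runif(length(lower)) *
                              (upper - lower))))
  Cs <- scale01(cand)
  Kc <- k(Cs, Xs)
  pred_mu <- drop(Kc %*% Ki %*% ys)
  pred_var <- pmax(1 - rowSums((Kc %*% Ki) * Kc), 1e-12)
  s <- sqrt(pred_var)
  best <- min(ys)
  imp <- best - pred_mu
  zsc <- imp / s
  ei <- imp * stats::pnorm(zsc) + s * stats::dnorm(zsc)
  cand[which.max(ei), ]
}

#' Project an independent trajectory through a trained model
#'
#' Encodes unseen contact maps with frozen weights and reports the
#' misprediction fraction (share of unpadded pixels reconstructed more than
#' `threshold` from their true binary value), for comparison with the
#' training trajectory's held-out fraction.
#'
#' @param model a trained [CVAEModel-class].
#' @param newMaps a [ContactMapSeries-class] with the same residue count and
#'   padding as the training maps.
#' @param seed integer seed for the latent sample.
#' @param threshold misprediction tolerance on the contact scale.
#' @return list with elements `embedding` (a [LatentEmbedding-class]) and
#'   `mispredictionFraction`.
#' @export
transferProject <- function(model, newMaps, seed = 1, threshold = 0.1) {
  stopifnot(is(model, "CVAEModel"))
  check_shape(model, newMaps)
  emb <- encodeMaps(model, newMaps, seed = seed)
  diff <- reconstructionDifference(model, newMaps, threshold = threshold)
  list(embedding = emb, mispredictionFraction = mispredictionFraction(diff))
}

#' Save / load a model checkpoint
#'
#' Single-file checkpoint holding hyperparameters, weights, input size and
#' the loss trace.
#'
#' @param model a [CVAEModel-class].
#' @param path checkpoint file path.
#' @return `saveModel` returns `path` invisibly; `loadModel` returns the
#'   [CVAEModel-class].
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "CVAEModel"))
  saveRDS(model, path, compress = "gzip")
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  obj <- readRDS(path)
  if (!is(obj, "CVAEModel"))
    stop("file does not contain a CVAEModel: ", path)
  obj
}
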