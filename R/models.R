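#' Construct a fully-connected feed-forward network
#'
#' General constructor behind [makeMLP()] and [makeAutoencoder()]. Weights
#' are initialized with the Glorot uniform scheme
#' (U(-sqrt(6/(fanIn+fanOut)), +sqrt(6/(fanIn+fanOut)))), biases at zero;
#' initialization is deterministic under `seed`.
#'
#' @param layerSizes integer vector of layer widths, input first. A network
#'   with `length(layerSizes) - 1` weight layers is built.
#' @param activation hidden-layer activation: `"relu"` (default) or
#'   `"identity"`. The output layer is linear.
#' @param task `"classification"` or `"reconstruction"`.
#' @param seed integer seed for the weight initialization.
#' @return A [DiffModel-class] object.
#' @export
feedForwardNet <- function(layerSizes, activation = c("relu", "identity"),
                           task = c("classification", "reconstruction"),
                           seed = 0L) {
  activation <- match.arg(activation)
  task <- match.arg(task)
  layerSizes <- vapply(layerSizes, .assertCount, integer(1),
                       name = "layerSizes")
  if (length(layerSizes) < 2L) stop("need at least input and output layers")
  L <- length(layerSizes) - 1L
  weights <- vector("list", L)
  biases <- vector("list", L)
  withSeed(seed, {
    for (l in seq_len(L)) {
      fanIn <- layerSizes[l]
      fanOut <- layerSizes[l + 1L]
      lim <- sqrt(6 / (fanIn + fanOut))
      weights[[l]] <- matrix(runif(fanIn * fanOut, -lim, lim), fanIn, fanOut)
      biases[[l]] <- numeric(fanOut)
    }
  })
  new("DiffModel", weights = weights, biases = biases,
      activation = activation, task = task,
      descriptor = list(layerSizes = as.integer(layerSizes),
                        activation = activation, task = task,
                        seed = as.integer(seed)))
}

#' Two-layer MLP classifier
#'
#' Builds the classification architecture used throughout: input ->
#' hidden (ReLU) -> class logits, trained with softmax cross-entropy.
#' Binary problems use two output units so multi-class tasks are handled
#' uniformly.
#'
#' @param inputDim number of input features.
#' @param hiddenDim hidden-layer width (default 100).
#' @param nClasses number of classes (>= 2).
#' @param seed initialization seed.
#' @return A [DiffModel-class] with two weight layers.
#' @examples
#' m <- makeMLP(4, hiddenDim = 8, nClasses = 2, seed = 0)
#' nParameters(m)  # 4*8 + 8 + 8*2 + 2 = 58
#' @export
makeMLP <- function(inputDim, hiddenDim = 100L, nClasses = 2L, seed = 0L) {
  inputDim <- .assertCount(inputDim, "inputDim")
  hiddenDim <- .assertCount(hiddenDim, "hiddenDim")
  nClasses <- .assertCount(nClasses, "nClasses", min = 2L)
  feedForwardNet(c(inputDim, hiddenDim, nClasses), activation = "relu",
                 task = "classification", seed = seed)
}

#' Two-layer autoencoder
#'
#' Encoder and decoder each have two weight layers; the single hidden
#' width is the rounded geometric mean of `inputDim` and `latentDim`, a
#' deterministic scale-free interpolation. Default latent width is 32.
#'
#' @param inputDim number of input features (e.g. 978 landmark genes).
#' @param latentDim bottleneck width, must be smaller than `inputDim`.
#' @param hiddenDim optional override of the encoder/decoder hidden width.
#' @param seed initialization seed.
#' @return A [DiffModel-class] with four weight layers whose output
#'   dimensionality equals `inputDim`.
#' @export
makeAutoencoder <- function(inputDim, latentDim = 32L, hiddenDim = NULL,
                            seed = 0L) {
  inputDim <- .assertCount(inputDim, "inputDim")
  latentDim <- .assertCount(latentDim, "latentDim")
  if (latentDim >= inputDim) {
    stop("'latentDim' must be smaller than 'inputDim'")
  }
  if (is.null(hiddenDim)) {
    hiddenDim <- max(latentDim, as.integer(round(sqrt(inputDim * latentDim))))
  }
  hiddenDim <- .assertCount(hiddenDim, "hiddenDim")
  feedForwardNet(c(inputDim, hiddenDim, latentDim, hiddenDim, inputDim),
                 activation = "relu", task = "reconstruction", seed = seed)
}

#' Loss specification constructor
#'
#' @param name `"cross_entropy"` or `"mse_reconstruction"`.
#' @param classWeights optional per-class non-negative weights for the
#'   cross-entropy loss.
#' @return A [LossSpec-class].
#' @export
lossSpec <- function(name = c("cross_entropy", "mse_reconstruction"),
                     classWeights = NULL) {
  name <- match.arg(name)
  new("LossSpec", name = name,
      classWeights = if (is.null(classWeights)) numeric() else as.numeric(classWeights))
}

.defaultLoss <- function(model) {
  if (model@task == "classification") lossSpec("cross_entropy")
  else lossSpec("mse_reconstruction")
}

#' Number of trainable parameters
#' @param model a [DiffModel-class].
#' @return integer parameter count.
#' @export
nParameters <- function(model) {
  sum(vapply(model@weights, length, integer(1))) +
    sum(vapply(model@biases, length, integer(1)))
}

#' Get the flattened parameter vector
#'
#' Column-major weights followed by biases, layer by layer — the fixed
#' ordering every gradient in the package uses.
#' @param model a [DiffModel-class].
#' @return numeric vector of length [nParameters()].
#' @export
modelParameters <- function(model) {
  unlist(lapply(seq_along(model@weights), function(l) {
    c(as.vector(model@weights[[l]]), model@biases[[l]])
  }), use.names = FALSE)
}

#' Replace the parameter vector
#' @param model a [DiffModel-class].
#' @param theta numeric vector in the [modelParameters()] ordering.
#' @return the updated model.
#' @export
setModelParameters <- function(model, theta) {
  if (length(theta) != nParameters(model)) {
    stop("parameter vector length mismatch")
  }
  pos <- 0L
  for (l in seq_along(model@weights)) {
    nw <- length(model@weights[[l]])
    nb <- length(model@biases[[l]])
    model@weights[[l]][] <- theta[pos + seq_len(nw)]
    model@biases[[l]] <- theta[pos + nw + seq_len(nb)]
    pos <- pos + nw + nb
  }
  model
}

.act <- function(Z, activation) {
  if (activation == "relu") pmax(Z, 0) else Z
}

.actGradMask <- function(Z, activation) {
  if (activation == "relu") (Z > 0) * 1 else array(1, dim(Z))
}

# Forward pass caching activations. X: n x d. Returns list(A, Z) where
# A[[1]] = X and A[[L+1]] = linear output.
.forward <- function(model, X) {
  L <- length(model@weights)
  A <- vector("list", L + 1L)
  Z <- vector("list", L)
  A[[1L]] <- X
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(A[[l]] %*% model@weights[[l]], 2L, model@biases[[l]], "+")
    A[[l + 1L]] <- if (l < L) .act(Z[[l]], model@activation) else Z[[l]]
  }
  list(A = A, Z = Z)
}

.softmax <- function(O) {
  E <- exp(O - apply(O, 1L, max))
  E / rowSums(E)
}

.checkInputDim <- function(model, X) {
  if (ncol(X) != nrow(model@weights[[1L]])) {
    stop(sprintf("input has %d features but model expects %d",
                 ncol(X), nrow(model@weights[[1L]])), call. = FALSE)
  }
}

.asRowMatrix <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

#' Model predictions
#'
#' Class probabilities (classification) or reconstructions.
#'
#' @param model a [DiffModel-class].
#' @param X feature matrix (samples x features) or a single feature vector.
#' @return numeric matrix: samples x classes (softmax probabilities) or
#'   samples x features (reconstruction).
#' @export
predictModel <- function(model, X) {
  X <- .asRowMatrix(X)
  .checkInputDim(model, X)
  O <- .forward(model, X)$A[[length(model@weights) + 1L]]
  if (model@task == "classification") .softmax(O) else O
}

.resolveClassWeights <- function(loss, nClasses) {
  w <- loss@classWeights
  if (!length(w)) return(rep(1, nClasses))
  if (length(w) != nClasses) {
    stop(sprintf("classWeights length %d but model has %d classes",
                 length(w), nClasses), call. = FALSE)
  }
  w
}

# Per-sample losses, vectorized over the rows of X. y: 0-based class codes
# for classification; target matrix (defaults to X) for reconstruction.
.perSampleLossCore <- function(model, X, y, loss) {
  O <- .forward(model, X)$A[[length(model@weights) + 1L]]
  if (model@task == "classification") {
    if (is.null(y)) stop("labels required for classification loss")
    y <- as.integer(y)
    if (any(y < 0L | y >= ncol(O))) stop("labels must be in 0..nClasses-1")
    P <- .softmax(O)
    w <- .resolveClassWeights(loss, ncol(O))
    p <- P[cbind(seq_len(nrow(X)), y + 1L)]
    w[y + 1L] * (-log(pmax(p, 1e-300)))
  } else {
    Tm <- if (is.null(y)) X else .asRowMatrix(y)
    if (!all(dim(Tm) == dim(O))) stop("reconstruction target shape mismatch")
    rowMeans((O - Tm)^2)
  }
}

#' Per-sample loss
#'
#' Cross-entropy (optionally class-weighted) for classification, mean
#' squared error over features for reconstruction. Non-negative by
#' construction.
#'
#' @param model a [DiffModel-class].
#' @param X feature matrix or single feature vector.
#' @param y 0-based class codes (classification) or target matrix
#'   (reconstruction; defaults to `X` itself).
#' @param loss a [LossSpec-class]; defaults to the model task's loss.
#' @return numeric vector of per-sample losses.
#' @export
perSampleLoss <- function(model, X, y = NULL, loss = .defaultLoss(model)) {
  X <- .asRowMatrix(X)
  .checkInputDim(model, X)
  .perSampleLossCore(model, X, y, loss)
}

#' Batch loss
#'
#' The (weighted) mean of per-sample losses — the objective whose gradient
#' drives the SGD updates.
#'
#' @inheritParams perSampleLoss
#' @return scalar loss.
#' @export
batchLoss <- function(model, X, y = NULL, loss = .defaultLoss(model)) {
  mean(perSampleLoss(model, X, y, loss))
}

#' @describeIn DiffModel-class compact architecture summary.
#' @param object a `DiffModel`.
#' @export
setMethod("show", "DiffModel", function(object) {
  sizes <- object@descriptor$layerSizes
  cat(sprintf("DiffModel (%s): %s | activation=%s | %d parameters\n",
              object@task, paste(sizes, collapse = "-"),
              object@activation, nParameters(object)))
})
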