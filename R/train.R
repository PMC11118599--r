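# SGD training of DiffModel networks and the retrainable-learner wrappers
# used by the leave-one-out / Shapley baselines and filter-and-retrain.

#' Train a network by mini-batch SGD
#'
#' @param model a [DiffModel-class].
#' @param X training features (samples x features).
#' @param y 0-based class labels (classification) or `NULL`
#'   (reconstruction trains toward `X` itself).
#' @param epochs full passes over the data.
#' @param batchSize mini-batch size (capped at the sample count).
#' @param learningRate SGD step size.
#' @param seed seed for the shuffling stream.
#' @param loss optional [LossSpec-class] override.
#' @return the trained model.
#' @export
trainModel <- function(model, X, y = NULL, epochs = 20L, batchSize = 32L,
                       learningRate = 0.05, seed = 0L, loss = NULL) {
  X <- .asRowMatrix(X)
  .checkInputDim(model, X)
  if (is.null(loss)) loss <- .defaultLoss(model)
  n <- nrow(X)
  bs <- min(.assertCount(batchSize, "batchSize"), n)
  epochs <- .assertCount(epochs, "epochs", min = 0L)
  withSeed(seed, {
    for (e in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1L, n)]
        bX <- X[idx, , drop = FALSE]
        by <- if (is.null(y)) NULL else y[idx]
        g <- .batchGradList(model, bX, by, loss)
        model <- .sgdStep(model, g, learningRate)
      }
    }
  })
  model
}

#' Scoring metrics for fitted learners
#'
#' Computes a "higher is better" score of predictions against ground
#' truth: `"negmse"` (negative mean squared error), `"auroc"` (mid-rank
#' AUROC for binary labels; predictions are scores for class 1),
#' `"accuracy"`, or `"r2"` (reconstruction R-squared of a predicted matrix
#' against the observed matrix, pooled over all entries).
#'
#' @param predictions numeric vector or matrix from a learner's predict
#'   function.
#' @param y ground truth: labels, targets, or the observed matrix for
#'   `"r2"`.
#' @param metric metric name.
#' @return scalar score (higher is better).
#' @export
scorePredictions <- function(predictions, y,
                             metric = c("negmse", "auroc", "accuracy", "r2")) {
  metric <- match.arg(metric)
  switch(metric,
    negmse = -mean((as.numeric(predictions) - as.numeric(y))^2),
    auroc = .aurocRank(as.numeric(predictions), y == 1L),
    accuracy = mean(as.numeric(predictions >= 0.5) == as.numeric(y)),
    r2 = {
      P <- as.matrix(predictions)
      Y <- as.matrix(y)
      1 - sum((P - Y)^2) / sum((Y - mean(Y))^2)
    }
  )
}

#' Fit a learner
#' @param learner a [Learner-class].
#' @param X,y training data (`NULL`/empty X gives the uninformed state).
#' @param seed fitting seed.
#' @return opaque fitted state.
#' @export
fitLearner <- function(learner, X, y = NULL, seed = 0L) {
  if (is.null(X) || nrow(.asRowMatrix(X)) == 0L) return(learner@nullFun())
  learner@fitFun(.asRowMatrix(X), y, seed)
}

#' Score a fitted learner on an evaluation set
#' @param learner a [Learner-class].
#' @param state fitted state from [fitLearner()].
#' @param X,y evaluation data.
#' @param metric metric name, see [scorePredictions()].
#' @return scalar score (higher is better).
#' @export
scoreLearner <- function(learner, state, X, y = NULL,
                         metric = c("negmse", "auroc", "accuracy", "r2")) {
  metric <- match.arg(metric)
  X <- .asRowMatrix(X)
  if (nrow(X) == 0L) stop("evaluation set must be non-empty")
  pred <- learner@predictFun(state, X)
  truth <- if (metric == "r2") X else y
  scorePredictions(pred, truth, metric)
}

#' Constant-mean regressor
#'
#' Predicts the training-target mean regardless of features; its
#' leave-one-out and Shapley values have closed forms, which makes it the
#' reference learner for the baseline tests. The uninformed (empty-set)
#' state predicts 0.
#'
#' @return a [Learner-class].
#' @export
meanLearner <- function() {
  new("Learner", name = "mean",
      fitFun = function(X, y, seed) list(mu = mean(as.numeric(y))),
      predictFun = function(state, X) rep(state$mu, nrow(X)),
      nullFun = function() list(mu = 0))
}

#' MLP classification learner
#'
#' Wraps a seeded [makeMLP()] + [trainModel()] fit; predictions are the
#' softmax probability of class 1 (binary) or the probability matrix. The
#' uninformed state predicts uniform probabilities.
#'
#' @param hiddenDim hidden width.
#' @param nClasses number of classes.
#' @param epochs,batchSize,learningRate SGD settings for each (re)fit.
#' @return a [Learner-class].
#' @export
mlpLearner <- function(hiddenDim = 100L, nClasses = 2L, epochs = 30L,
                       batchSize = 32L, learningRate = 0.05) {
  new("Learner", name = "mlp",
      fitFun = function(X, y, seed) {
        if (length(unique(y)) < 2L) {
          stop("degenerate training set: only one class present")
        }
        m <- makeMLP(ncol(X), hiddenDim = hiddenDim, nClasses = nClasses,
                     seed = seed)
        trainModel(m, X, y, epochs = epochs, batchSize = batchSize,
                   learningRate = learningRate, seed = seed)
      },
      predictFun = function(state, X) {
        if (is.null(state)) return(rep(1 / nClasses, nrow(X)))
        P <- predictModel(state, X)
        if (ncol(P) == 2L) P[, 2L] else P
      },
      nullFun = function() NULL)
}

#' Autoencoder reconstruction learner
#'
#' Wraps a seeded [makeAutoencoder()] + [trainModel()] fit; predictions
#' are reconstructions, scored with the `"r2"` metric. The uninformed
#' state reconstructs everything as 0.
#'
#' @param latentDim bottleneck width.
#' @param epochs,batchSize,learningRate SGD settings for each (re)fit.
#' @return a [Learner-class].
#' @export
autoencoderLearner <- function(latentDim = 32L, epochs = 30L, batchSize = 32L,
                               learningRate = 0.05) {
  new("Learner", name = "autoencoder",
      fitFun = function(X, y, seed) {
        m <- makeAutoencoder(ncol(X), latentDim = min(latentDim, ncol(X) - 1L),
                             seed = seed)
        trainModel(m, X, NULL, epochs = epochs, batchSize = batchSize,
                   learningRate = learningRate, seed = seed)
      },
      predictFun = function(state, X) {
        if (is.null(state)) matrix(0, nrow(X), ncol(X)) else
          predictModel(state, X)
      },
      nullFun = function() NULL)
}

setMethod("show", "Learner", function(object) {
  cat(sprintf("Learner: %s\n", object@name))
})
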