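# Backpropagation and per-sample gradient machinery. Gradients are kept
# internally as per-layer lists (W, b) and flattened with the same ordering
# as modelParameters().

# Per-sample output-layer deltas (unscaled by batch size). Rows of the
# returned matrix are d loss_i / d output_i.
.outputDelta <- function(model, cache, X, y, loss) {
  O <- cache$A[[length(model@weights) + 1L]]
  if (model@task == "classification") {
    if (is.null(y)) stop("labels required for classification gradient")
    y <- as.integer(y)
    P <- .softmax(O)
    w <- .resolveClassWeights(loss, ncol(O))
    D <- P
    D[cbind(seq_len(nrow(O)), y + 1L)] <- D[cbind(seq_len(nrow(O)), y + 1L)] - 1
    D * w[y + 1L]
  } else {
    Tm <- if (is.null(y)) X else .asRowMatrix(y)
    2 * (O - Tm) / ncol(O)
  }
}

# Backpropagate per-sample deltas into summed per-layer gradients;
# `scale` multiplies the deltas (1/n gives the batch-mean gradient).
.backprop <- function(model, cache, D, scale = 1) {
  L <- length(model@weights)
  D <- D * scale
  gW <- vector("list", L)
  gb <- vector("list", L)
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(cache$A[[l]], D)
    gb[[l]] <- colSums(D)
    if (l > 1L) {
      D <- (D %*% t(model@weights[[l]])) * .actGradMask(cache$Z[[l - 1L]],
                                                        model@activation)
    }
  }
  list(W = gW, b = gb)
}

.flattenGrad <- function(g) {
  unlist(lapply(seq_along(g$W), function(l) c(as.vector(g$W[[l]]), g$b[[l]])),
         use.names = FALSE)
}

.unflattenGrad <- function(model, v) {
  pos <- 0L
  gW <- vector("list", length(model@weights))
  gb <- vector("list", length(model@weights))
  for (l in seq_along(model@weights)) {
    nw <- length(model@weights[[l]])
    nb <- length(model@biases[[l]])
    gW[[l]] <- matrix(v[pos + seq_len(nw)], nrow(model@weights[[l]]),
                      ncol(model@weights[[l]]))
    gb[[l]] <- v[pos + nw + seq_len(nb)]
    pos <- pos + nw + nb
  }
  list(W = gW, b = gb)
}

.batchGradList <- function(model, X, y, loss) {
  cache <- .forward(model, X)
  D <- .outputDelta(model, cache, X, y, loss)
  .backprop(model, cache, D, scale = 1 / nrow(X))
}

.sgdStep <- function(model, grad, lr) {
  for (l in seq_along(model@weights)) {
    model@weights[[l]] <- model@weights[[l]] - lr * grad$W[[l]]
    model@biases[[l]] <- model@biases[[l]] - lr * grad$b[[l]]
  }
  model
}

#' Class-balancing weights
#'
#' Weights inversely proportional to class frequency, `n / (K * n_c)`, so
#' that each class contributes equally to a weighted-mean loss. Classes
#' absent from `y` get weight 0.
#'
#' @param y 0-based integer class codes.
#' @param nClasses number of classes.
#' @return numeric weight vector of length `nClasses`.
#' @export
balancedClassWeights <- function(y, nClasses) {
  y <- as.integer(y)
  counts <- tabulate(y + 1L, nbins = nClasses)
  w <- numeric(nClasses)
  present <- counts > 0L
  w[present] <- length(y) / (nClasses * counts[present])
  w
}

#' Gradient of the batch loss
#'
#' Gradient of the (weighted) mean per-sample loss over a batch with
#' respect to all trainable parameters, flattened in the
#' [modelParameters()] ordering. With `classBalance = TRUE` per-sample
#' losses are weighted inversely to class frequency (computed from the
#' batch unless explicit `classWeights` are supplied) so each class
#' contributes equally — the recommended setting for target gradients on
#' imbalanced targets.
#'
#' @param model a [DiffModel-class].
#' @param X batch feature matrix (non-empty).
#' @param y labels / reconstruction targets (see [perSampleLoss()]).
#' @param loss a [LossSpec-class]; default derived from the model task.
#' @param classBalance logical; balance class contributions.
#' @param classWeights optional explicit per-class weights (overrides
#'   `classBalance`).
#' @return numeric gradient vector of length [nParameters()].
#' @export
targetBatchGradient <- function(model, X, y = NULL, loss = NULL,
                                classBalance = FALSE, classWeights = NULL) {
  X <- .asRowMatrix(X)
  if (nrow(X) == 0L) stop("batch must be non-empty")
  .checkInputDim(model, X)
  if (is.null(loss)) loss <- .defaultLoss(model)
  if (model@task == "classification") {
    if (!is.null(classWeights)) {
      loss@classWeights <- as.numeric(classWeights)
    } else if (classBalance) {
      nC <- ncol(model@weights[[length(model@weights)]])
      loss@classWeights <- balancedClassWeights(y, nC)
    }
  }
  .flattenGrad(.batchGradList(model, X, y, loss))
}

#' Per-sample loss gradients
#'
#' Exact gradient of each sample's loss with respect to all trainable
#' parameters, one flattened row per sample. This is the explicit
#' (materializing) path; [gradientSimilarities()] provides an equivalent
#' vectorized path that never forms the per-sample matrix.
#'
#' @inheritParams targetBatchGradient
#' @return numeric matrix, samples x parameters.
#' @export
perSampleGradients <- function(model, X, y = NULL, loss = .defaultLoss(model)) {
  X <- .asRowMatrix(X)
  .checkInputDim(model, X)
  n <- nrow(X)
  out <- matrix(0, n, nParameters(model))
  for (i in seq_len(n)) {
    Xi <- X[i, , drop = FALSE]
    yi <- if (is.null(y)) NULL else if (model@task == "classification") y[i] else
      .asRowMatrix(y)[i, , drop = FALSE]
    li <- .perSampleLossCore(model, Xi, yi, loss)
    if (!is.finite(li)) stop(sprintf("non-finite loss for sample %d", i))
    cache <- .forward(model, Xi)
    D <- .outputDelta(model, cache, Xi, yi, loss)
    out[i, ] <- .flattenGrad(.backprop(model, cache, D))
  }
  out
}

#' Cosine similarity of two gradient vectors
#'
#' `dot(a, b) / (||a|| ||b||)`, bounded in [-1, 1] and invariant to
#' positive rescaling of either argument. When either vector has zero
#' norm the similarity is defined as 0 (no directional information).
#'
#' @param a,b numeric vectors of equal length with finite entries.
#' @return scalar in [-1, 1].
#' @export
cosineSimilarity <- function(a, b) {
  if (length(a) != length(b)) stop("gradient vectors differ in length")
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    stop("gradient vectors must be finite")
  }
  na <- sqrt(sum(a * a))
  nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) return(0)
  max(-1, min(1, sum(a * b) / (na * nb)))
}

# Vectorized per-sample similarity computation. For layer l the per-sample
# gradient is the outer product a_{l-1,i} (x) delta_{l,i} plus delta_{l,i}
# for the bias, so dot products with a reference gradient and per-sample
# norms reduce to dense matrix products — no per-sample gradient matrix is
# ever materialized.
.similaritiesFast <- function(model, X, y, loss, refList, refFlat,
                              similarity = "cosine") {
  L <- length(model@weights)
  cache <- .forward(model, X)
  D <- .outputDelta(model, cache, X, y, loss)
  dots <- numeric(nrow(X))
  norms2 <- numeric(nrow(X))
  for (l in rev(seq_len(L))) {
    A <- cache$A[[l]]
    dots <- dots + rowSums((A %*% refList$W[[l]]) * D) +
      as.vector(D %*% refList$b[[l]])
    norms2 <- norms2 + rowSums(D * D) * (rowSums(A * A) + 1)
    if (l > 1L) {
      D <- (D %*% t(model@weights[[l]])) * .actGradMask(cache$Z[[l - 1L]],
                                                        model@activation)
    }
  }
  refNorm <- sqrt(sum(refFlat^2))
  if (similarity == "cosine") {
    denom <- sqrt(norms2) * refNorm
    s <- ifelse(denom == 0, 0, dots / denom)
    pmax(-1, pmin(1, s))
  } else if (similarity == "dot") {
    dots
  } else { # negative Euclidean distance
    -sqrt(pmax(norms2 - 2 * dots + refNorm^2, 0))
  }
}

#' Similarity of each sample's gradient to a reference gradient
#'
#' Computes, for every row of `X`, the similarity between that sample's
#' loss gradient and a reference gradient (typically a target-batch
#' gradient). Two equivalent paths are provided: `"fast"` (vectorized,
#' never materializes per-sample gradients) and `"loop"` (explicit
#' per-sample gradients via [perSampleGradients()]); they agree to
#' numerical precision and the loop path serves as the reference
#' implementation.
#'
#' @inheritParams targetBatchGradient
#' @param refGrad reference gradient: flattened numeric vector.
#' @param similarity `"cosine"` (default, bounded in [-1,1]), `"dot"`, or
#'   `"euclidean"` (negative distance; provided for experimentation,
#'   unvalidated).
#' @param method `"fast"` or `"loop"`.
#' @return numeric vector of similarities, one per row of `X`.
#' @export
gradientSimilarities <- function(model, X, y = NULL, refGrad,
                                 loss = .defaultLoss(model),
                                 similarity = c("cosine", "dot", "euclidean"),
                                 method = c("fast", "loop")) {
  similarity <- match.arg(similarity)
  method <- match.arg(method)
  X <- .asRowMatrix(X)
  .checkInputDim(model, X)
  if (length(refGrad) != nParameters(model)) {
    stop("reference gradient length must equal the model parameter count")
  }
  if (method == "fast") {
    refList <- .unflattenGrad(model, refGrad)
    .similaritiesFast(model, X, y, loss, refList, refGrad, similarity)
  } else {
    G <- perSampleGradients(model, X, y, loss)
    switch(similarity,
      cosine = apply(G, 1L, cosineSimilarity, b = refGrad),
      dot = as.vector(G %*% refGrad),
      euclidean = -sqrt(rowSums(sweep(G, 2L, refGrad)^2))
    )
  }
}
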