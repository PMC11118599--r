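# Shared fixtures and independent oracles.

# Central finite-difference gradient of the mean per-sample loss at the
# current parameters; the reference all analytic gradients are checked
# against.
numericGradient <- function(model, X, y = NULL, loss = NULL, eps = 1e-5) {
  if (is.null(loss)) loss <- dvgs:::.defaultLoss(model)
  theta <- modelParameters(model)
  vapply(seq_along(theta), function(p) {
    tp <- theta
    tp[p] <- theta[p] + eps
    up <- batchLoss(setModelParameters(model, tp), X, y, loss)
    tp[p] <- theta[p] - eps
    dn <- batchLoss(setModelParameters(model, tp), X, y, loss)
    (up - dn) / (2 * eps)
  }, numeric(1))
}

# Small labeled blob split used across tests.
smallSplit <- function(n = 200, d = 6, separation = 4, seed = 42,
                       nTarget = 60) {
  tab <- makeBlobs(n + nTarget, d, separation = separation, seed = seed)
  X <- features(tab)
  y <- classLabels(tab)
  list(src = list(X = X[seq_len(n), , drop = FALSE], y = y[seq_len(n)]),
       tgt = list(X = X[n + seq_len(nTarget), , drop = FALSE],
                  y = y[n + seq_len(nTarget)]))
}

# Closed-form scores of the constant-mean regressor under negative MSE:
# value function v(S) = -mean((mean(y_S) - y_target)^2), v(empty) = 0
# prediction.
meanPredictorScore <- function(trainY, targetY) {
  mu <- if (length(trainY) == 0L) 0 else mean(trainY)
  -mean((mu - targetY)^2)
}

# Brute-force Shapley values for the constant-mean regressor by direct
# enumeration over all permutations, independent of the package's
# estimator code.
bruteForceShapleyMean <- function(sourceY, targetY) {
  n <- length(sourceY)
  perms <- NULL
  permute <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in permute(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  allp <- permute(seq_len(n))
  sums <- numeric(n)
  for (perm in allp) {
    prev <- meanPredictorScore(numeric(), targetY)
    for (j in seq_along(perm)) {
      cur <- meanPredictorScore(sourceY[perm[seq_len(j)]], targetY)
      sums[perm[j]] <- sums[perm[j]] + cur - prev
      prev <- cur
    }
  }
  sums / length(allp)
}
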