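# Artificial data-quality defects with retained ground truth: flipped
# class labels and per-sample Gaussian feature noise.

#' Flip a proportion of class labels
#'
#' Chooses `round(proportion * n)` samples uniformly without replacement
#' and replaces each of their labels with a label drawn uniformly from the
#' other classes (the flipped label always differs from the original).
#' Unselected labels are untouched. The returned mask (0 = uncorrupted,
#' 1 = corrupted) is the ground truth for corruption-discovery evaluation.
#'
#' @param y 0-based integer class labels.
#' @param proportion fraction of labels to corrupt, in [0, 1].
#' @param nClasses number of classes (>= 2); defaults to the number of
#'   distinct labels observed.
#' @param seed RNG seed.
#' @return `list(y = corrupted labels, mask = integer 0/1 vector)`.
#' @export
flipLabels <- function(y, proportion, nClasses = length(unique(y)),
                       seed = 0L) {
  y <- as.integer(y)
  proportion <- .assertScalar(proportion, "proportion", lower = 0, upper = 1)
  nClasses <- .assertCount(nClasses, "nClasses", min = 2L)
  if (any(y < 0L | y >= nClasses)) stop("labels must be in 0..nClasses-1")
  n <- length(y)
  nFlip <- as.integer(floor(proportion * n + 0.5))  # round half-up
  mask <- integer(n)
  if (nFlip > 0L) {
    withSeed(seed, {
      idx <- sample.int(n, nFlip)
      mask[idx] <- 1L
      for (i in idx) {
        others <- setdiff(0:(nClasses - 1L), y[i])
        y[i] <- others[sample.int(length(others), 1L)]
      }
    })
  }
  list(y = y, mask = mask)
}

#' Add per-sample Gaussian feature noise
#'
#' Each sample i gets a noise rate `phi_i ~ Uniform(low, high)`; every
#' feature of that sample is perturbed by independent Gaussian noise with
#' mean 0 and standard deviation `phi_i`, so samples with larger rates
#' carry noise of greater variance. Rates are the ground truth for the
#' noise-quantification evaluation.
#'
#' @param X samples x features numeric matrix.
#' @param rateRange `c(low, high)` of the uniform the rates are drawn
#'   from; `0 <= low <= high`. The default Uniform(0, 1) is comparable in
#'   magnitude to standardized (unit-variance) features at the top of the
#'   range.
#' @param seed RNG seed.
#' @return `list(X = corrupted matrix, rates = numeric vector phi,
#'   rateRange = rateRange)`.
#' @export
addFeatureNoise <- function(X, rateRange = c(0, 1), seed = 0L) {
  X <- .asRowMatrix(X)
  if (length(rateRange) != 2L) stop("'rateRange' must be c(low, high)")
  low <- .assertScalar(rateRange[1], "rateRange[1]", lower = 0)
  high <- .assertScalar(rateRange[2], "rateRange[2]", lower = low)
  n <- nrow(X)
  d <- ncol(X)
  withSeed(seed, {
    rates <- runif(n, low, high)
    if (high > 0) {
      noise <- matrix(rnorm(n * d), n, d) * rates
      X <- X + noise
    }
  })
  list(X = X, rates = rates, rateRange = c(low, high))
}
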