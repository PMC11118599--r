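# Baseline valuation methods: random (null model), leave-one-out, and
# truncated Monte-Carlo Data Shapley, plus the exhaustive Shapley
# computation used as an oracle on tiny problems.

#' Random data values (null model)
#'
#' Values drawn independently from Uniform(0, 1); the null baseline whose
#' corruption-discovery AUROC is 0.5 and noise-rate Spearman is 0 in
#' expectation.
#'
#' @param n number of samples (>= 1).
#' @param seed RNG seed.
#' @return a [DataValues-class].
#' @export
randomValues <- function(n, seed = 0L) {
  n <- .assertCount(n, "n")
  vals <- withSeed(seed, runif(n))
  new("DataValues", values = vals, method = "random",
      params = list(seed = as.integer(seed)))
}

.scoreSubset <- function(learner, X, y, idx, evalX, evalY, metric, seed) {
  state <- if (length(idx) == 0L) learner@nullFun() else
    fitLearner(learner, X[idx, , drop = FALSE],
               if (is.null(y)) NULL else y[idx], seed = seed)
  scoreLearner(learner, state, evalX, evalY, metric)
}

#' Leave-one-out data values
#'
#' `v_k = score(fit(source), target) - score(fit(source \ k), target)`:
#' positive when removing the sample hurts target performance, matching
#' the "higher is better" orientation of the other methods. A sample whose
#' removal makes the refit degenerate (learner error) gets `NA` and the
#' run continues.
#'
#' @param learner a [Learner-class].
#' @param source,target datasets ([LabeledTable-class], matrix, or
#'   `list(X, y)`); source needs >= 2 samples.
#' @param metric score metric, see [scorePredictions()].
#' @param seed fitting seed.
#' @return a [DataValues-class] (with `extra$fullScore`).
#' @export
looValues <- function(learner, source, target, metric = "negmse", seed = 0L) {
  src <- .asXY(source, "source")
  tgt <- .asXY(target, "target")
  n <- nrow(src$X)
  if (n < 2L) stop("leave-one-out needs at least 2 source samples")
  full <- .scoreSubset(learner, src$X, src$y, seq_len(n), tgt$X, tgt$y,
                       metric, seed)
  vals <- vapply(seq_len(n), function(k) {
    s <- tryCatch(
      .scoreSubset(learner, src$X, src$y, setdiff(seq_len(n), k),
                   tgt$X, tgt$y, metric, seed),
      error = function(e) NA_real_)
    full - s
  }, numeric(1))
  names(vals) <- src$ids
  new("DataValues", values = vals, method = "loo",
      params = list(metric = metric, seed = as.integer(seed)),
      extra = list(fullScore = full))
}

#' Truncated Monte-Carlo Shapley configuration
#'
#' @param maxPermutations permutation budget.
#' @param truncationTolerance a permutation is truncated once the running
#'   score is within this tolerance of the full-data score (`NULL` =
#'   `0.01 * |score(full)|`).
#' @param convergenceTolerance stop early when every value changed less
#'   than this over the last 10 permutations.
#' @param exhaustive enumerate all `n!` permutations once instead of
#'   sampling (tiny sources only, n <= 8); with `truncationTolerance = 0`
#'   this reproduces exact Shapley values.
#' @param seed permutation-sampling seed.
#' @return a named list of validated settings.
#' @export
shapleyConfig <- function(maxPermutations = 200L, truncationTolerance = NULL,
                          convergenceTolerance = 0.001, exhaustive = FALSE,
                          seed = 0L) {
  list(
    maxPermutations = .assertCount(maxPermutations, "maxPermutations"),
    truncationTolerance = if (is.null(truncationTolerance)) NULL else
      .assertScalar(truncationTolerance, "truncationTolerance", lower = 0),
    convergenceTolerance = .assertScalar(convergenceTolerance,
                                         "convergenceTolerance", lower = 0),
    exhaustive = isTRUE(exhaustive),
    seed = .assertCount(seed, "seed", min = 0L)
  )
}

#' Truncated Monte-Carlo Data Shapley values
#'
#' Estimates each sample's Shapley value as its average marginal
#' contribution to the target score over random permutations of the
#' source set, truncating a permutation once the running score is within
#' `truncationTolerance` of the full-data score. The empty-set baseline is
#' the learner's uninformed prediction. Stops at `maxPermutations` or when
#' all running means stabilize within `convergenceTolerance` over the last
#' 10 permutations; `extra$converged` records which.
#'
#' @inheritParams looValues
#' @param config a [shapleyConfig()] list.
#' @return a [DataValues-class] with `extra$converged`,
#'   `extra$nPermutations`, `extra$fullScore` and `extra$nullScore`.
#' @export
tmcShapley <- function(learner, source, target, metric = "negmse",
                       config = shapleyConfig()) {
  src <- .asXY(source, "source")
  tgt <- .asXY(target, "target")
  n <- nrow(src$X)
  if (n < 2L) stop("Shapley valuation needs at least 2 source samples")
  fullScore <- .scoreSubset(learner, src$X, src$y, seq_len(n), tgt$X, tgt$y,
                            metric, config$seed)
  nullScore <- .scoreSubset(learner, src$X, src$y, integer(), tgt$X, tgt$y,
                            metric, config$seed)
  tol <- if (is.null(config$truncationTolerance)) 0.01 * abs(fullScore) else
    config$truncationTolerance
  allPerms <- NULL
  maxP <- config$maxPermutations
  if (isTRUE(config$exhaustive)) {
    if (n > 8L) stop("exhaustive enumeration supported only for n <= 8")
    allPerms <- .allPermutations(n)
    maxP <- nrow(allPerms)
  }
  sums <- numeric(n)
  history <- matrix(NA_real_, n, 10L)
  converged <- FALSE
  p <- 0L
  withSeed(config$seed, {
    while (p < maxP) {
      p <- p + 1L
      perm <- if (is.null(allPerms)) sample.int(n) else allPerms[p, ]
      prev <- nullScore
      truncated <- FALSE
      for (j in seq_len(n)) {
        if (!truncated && abs(fullScore - prev) < tol) truncated <- TRUE
        if (truncated) {
          marg <- 0
        } else {
          cur <- tryCatch(
            .scoreSubset(learner, src$X, src$y, perm[seq_len(j)],
                         tgt$X, tgt$y, metric, config$seed),
            error = function(e) prev)
          marg <- cur - prev
          prev <- cur
        }
        sums[perm[j]] <- sums[perm[j]] + marg
      }
      means <- sums / p
      history <- cbind(history[, -1L, drop = FALSE], means)
      if (p > 10L && is.null(allPerms)) {
        drift <- apply(abs(history - means), 1L, max)
        if (all(drift < config$convergenceTolerance)) {
          converged <- TRUE
          break
        }
      }
    }
  })
  vals <- sums / p
  names(vals) <- src$ids
  new("DataValues", values = vals, method = "shapley",
      params = c(config, list(metric = metric)),
      extra = list(converged = converged || isTRUE(config$exhaustive),
                   nPermutations = p,
                   fullScore = fullScore, nullScore = nullScore))
}

#' Exact Shapley values by exhaustive enumeration
#'
#' Averages marginal contributions over all `n!` permutations; tractable
#' only for tiny source sets (guarded at n <= 8). Serves as the oracle the
#' Monte-Carlo estimator is checked against.
#'
#' @inheritParams looValues
#' @return a [DataValues-class].
#' @export
exactShapley <- function(learner, source, target, metric = "negmse",
                         seed = 0L) {
  src <- .asXY(source, "source")
  tgt <- .asXY(target, "target")
  n <- nrow(src$X)
  if (n < 2L || n > 8L) stop("exact Shapley supported for 2 <= n <= 8")
  perms <- .allPermutations(n)
  nullScore <- .scoreSubset(learner, src$X, src$y, integer(), tgt$X, tgt$y,
                            metric, seed)
  sums <- numeric(n)
  for (pi in seq_len(nrow(perms))) {
    perm <- perms[pi, ]
    prev <- nullScore
    for (j in seq_len(n)) {
      cur <- .scoreSubset(learner, src$X, src$y, perm[seq_len(j)],
                          tgt$X, tgt$y, metric, seed)
      sums[perm[j]] <- sums[perm[j]] + (cur - prev)
      prev <- cur
    }
  }
  vals <- sums / nrow(perms)
  names(vals) <- src$ids
  new("DataValues", values = vals, method = "shapley_exact",
      params = list(metric = metric, seed = as.integer(seed)))
}

.allPermutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .allPermutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, ifelse(sub >= k, sub + 1L, sub))
  }))
}
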