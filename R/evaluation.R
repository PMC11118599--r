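# Evaluation statistics: corruption-discovery AUROC, noise-rate Spearman,
# filter-and-retrain curves, and the replicate APC quality metric.

#' Corruption-discovery AUROC
#'
#' AUROC of the negated data values, `AUROC(c, -v)`, as a detector of the
#' corruption mask (0 = uncorrupted, 1 = corrupted): the sign flip encodes
#' the expectation that corrupted samples receive LOW values. Computed by
#' mid-rank Mann-Whitney, so it is invariant under strictly monotone
#' transforms of the values and handles ties.
#'
#' @param mask 0/1 corruption ground truth (both classes must occur).
#' @param values a [DataValues-class] or numeric vector, same length.
#' @return AUROC in [0, 1]; 1 means corrupted samples have exactly the
#'   lowest values.
#' @export
corruptionAUROC <- function(mask, values) {
  v <- .valuesVector(values)
  mask <- as.integer(mask)
  if (length(mask) != length(v)) stop("mask and values differ in length")
  if (!all(mask %in% c(0L, 1L))) stop("mask must be 0/1")
  .aurocRank(-v, mask == 1L)
}

#' Noise-rate Spearman correlation
#'
#' `Spearman(phi, -v)`: rank correlation between per-sample noise rates
#' and negated data values; positive when noisier samples get lower
#' values. Invariant under strictly monotone transforms of either
#' argument.
#'
#' @param rates per-sample noise rates phi (>= 3 samples).
#' @param values a [DataValues-class] or numeric vector, same length.
#' @return correlation in [-1, 1].
#' @export
noiseSpearman <- function(rates, values) {
  v <- .valuesVector(values)
  rates <- as.numeric(rates)
  if (length(rates) != length(v)) stop("rates and values differ in length")
  if (length(v) < 3L) stop("need at least 3 samples")
  if (sd(rates) == 0 || sd(v) == 0) {
    stop("Spearman undefined for constant input")
  }
  cor(rates, -v, method = "spearman")
}

#' Filter-and-retrain performance curve
#'
#' For each fraction q, removes the `floor(q * n)` source samples with the
#' lowest (or highest) data values, retrains the learner on the remainder
#' (`reps` independent seeded fits), and scores the held-out test set.
#' Removing low-value data is expected to maintain or improve performance
#' when values capture quality; removing high-value data should degrade
#' it. Ties at the cutoff are broken by a seeded random order so exactly
#' `floor(q * n)` samples are removed.
#'
#' @param values a [DataValues-class] or numeric vector over the source
#'   samples.
#' @param source training pool being filtered.
#' @param test held-out evaluation set.
#' @param learner a [Learner-class].
#' @param metric score metric, see [scorePredictions()].
#' @param fractions increasing removal fractions in [0, 1), starting at 0.
#' @param direction `"remove_lowest"` or `"remove_highest"`.
#' @param reps independent retrain replicates per fraction.
#' @param seed seed for tie-breaking and the replicate fits.
#' @return a [FilterCurve-class] (scores: reps x fractions).
#' @export
filterAndRetrain <- function(values, source, test, learner, metric = "auroc",
                             fractions = seq(0, 0.5, by = 0.1),
                             direction = c("remove_lowest", "remove_highest"),
                             reps = 1L, seed = 0L) {
  direction <- match.arg(direction)
  v <- .valuesVector(values)
  src <- .asXY(source, "source")
  tst <- .asXY(test, "test")
  n <- nrow(src$X)
  if (length(v) != n) stop("values length must equal source size")
  if (nrow(tst$X) == 0L) stop("test set must be non-empty")
  if (length(fractions) == 0L || fractions[1] != 0) {
    stop("fractions must start at 0")
  }
  if (any(diff(fractions) <= 0) || any(fractions >= 1)) {
    stop("fractions must be strictly increasing and < 1")
  }
  reps <- .assertCount(reps, "reps")
  # seeded random tie-break, then stable order by value
  tie <- withSeed(seed, sample.int(n))
  ord <- order(v, tie)                      # ascending values
  if (direction == "remove_highest") ord <- rev(ord)
  scores <- matrix(NA_real_, reps, length(fractions))
  for (fi in seq_along(fractions)) {
    q <- fractions[fi]
    nDrop <- as.integer(floor(q * n))
    keep <- sort(if (nDrop > 0L) ord[-seq_len(nDrop)] else ord)
    if (length(keep) == 0L) {
      stop(sprintf("fraction %.3f removes every training sample", q))
    }
    for (r in seq_len(reps)) {
      state <- tryCatch(
        fitLearner(learner, src$X[keep, , drop = FALSE],
                   if (is.null(src$y)) NULL else src$y[keep],
                   seed = seed + r),
        error = function(e) {
          stop(sprintf("retrain failed at fraction %.3f: %s", q,
                       conditionMessage(e)), call. = FALSE)
        })
      scores[r, fi] <- scoreLearner(learner, state, tst$X, tst$y, metric)
    }
  }
  new("FilterCurve", fractions = as.numeric(fractions),
      direction = direction, scores = scores, metricName = metric)
}

#' @describeIn FilterCurve-class removal fractions.
#' @param x a `FilterCurve`.
#' @export
curveFractions <- function(x) {
  stopifnot(is(x, "FilterCurve"))
  x@fractions
}

#' @describeIn FilterCurve-class replicate x fraction score matrix.
#' @export
curveScores <- function(x) {
  stopifnot(is(x, "FilterCurve"))
  x@scores
}

#' @describeIn FilterCurve-class tidy data.frame (fraction, rep, score).
#' @param row.names,optional,... ignored (S3 compatibility).
#' @export
as.data.frame.FilterCurve <- function(x, row.names = NULL, optional = FALSE,
                                      ...) {
  data.frame(
    fraction = rep(x@fractions, each = nrow(x@scores)),
    rep = rep(seq_len(nrow(x@scores)), times = length(x@fractions)),
    score = as.vector(x@scores),
    direction = x@direction,
    metric = x@metricName
  )
}

#' @describeIn FilterCurve-class compact summary.
#' @param object a `FilterCurve`.
#' @export
setMethod("show", "FilterCurve", function(object) {
  cat(sprintf("FilterCurve (%s, %s): %d fractions x %d reps\n",
              object@direction, object@metricName,
              length(object@fractions), nrow(object@scores)))
  cat("  mean scores:",
      paste(sprintf("%.3f", colMeans(object@scores)), collapse = " "), "\n")
})

#' Average Pearson correlation of replicates
#'
#' For each perturbation group, the unweighted mean of Pearson
#' correlations over all unordered pairs of replicate profiles. Groups
#' with fewer than two replicates get `NA`; pairs involving a constant
#' (zero-variance) profile are dropped from the mean and counted in
#' `nDroppedPairs`.
#'
#' @param expression a [ReplicateExpressionSet-class], or a replicates x
#'   genes numeric matrix.
#' @param groups replicate-to-group assignment (required for the matrix
#'   input, ignored for a `ReplicateExpressionSet`).
#' @return an [ApcResult-class].
#' @export
apc <- function(expression, groups = NULL) {
  if (is(expression, "ReplicateExpressionSet")) {
    M <- t(SummarizedExperiment::assay(expression, "level4"))
    groups <- as.character(SummarizedExperiment::colData(expression)$group)
  } else {
    M <- .asRowMatrix(expression)
    if (is.null(groups)) stop("'groups' is required for matrix input")
    groups <- as.character(groups)
  }
  if (length(groups) != nrow(M)) {
    stop("one group id per replicate row is required")
  }
  ids <- unique(groups)
  nRep <- integer(length(ids))
  dropped <- integer(length(ids))
  vals <- rep(NA_real_, length(ids))
  for (gi in seq_along(ids)) {
    rows <- which(groups == ids[gi])
    nRep[gi] <- length(rows)
    if (length(rows) < 2L) next
    sub <- M[rows, , drop = FALSE]
    ok <- apply(sub, 1L, sd) > 0
    pairCors <- c()
    nDrop <- 0L
    for (a in seq_len(length(rows) - 1L)) {
      for (b in (a + 1L):length(rows)) {
        if (ok[a] && ok[b]) {
          pairCors <- c(pairCors, cor(sub[a, ], sub[b, ]))
        } else {
          nDrop <- nDrop + 1L
        }
      }
    }
    dropped[gi] <- nDrop
    if (length(pairCors)) vals[gi] <- mean(pairCors)
  }
  if (all(nRep < 2L)) stop("need at least one group with >= 2 replicates")
  new("ApcResult", groupIds = ids, apc = vals, nReplicates = nRep,
      nDroppedPairs = dropped)
}

#' @describeIn ApcResult-class per-group APC values (named by group).
#' @param x an `ApcResult`.
#' @export
apcValues <- function(x) {
  stopifnot(is(x, "ApcResult"))
  stats::setNames(x@apc, x@groupIds)
}

#' @describeIn ApcResult-class compact summary.
#' @param object an `ApcResult`.
#' @export
setMethod("show", "ApcResult", function(object) {
  ok <- !is.na(object@apc)
  cat(sprintf("ApcResult: %d groups (%d with >= 2 replicates)\n",
              length(object@groupIds), sum(object@nReplicates >= 2L)))
  if (any(ok)) {
    cat(sprintf("  APC: min %.3f | median %.3f | max %.3f\n",
                min(object@apc[ok]), stats::median(object@apc[ok]),
                max(object@apc[ok])))
  }
})

#' Partition groups by APC threshold
#'
#' Strict-inequality split: groups with APC strictly above the threshold
#' are "high" quality, the rest (including the threshold itself) "low".
#' The conventional high-quality threshold is 0.5. Groups with undefined
#' (`NA`) APC are reported separately.
#'
#' @param apcResult an [ApcResult-class].
#' @param threshold split point in [-1, 1] (default 0.5).
#' @return `list(high = , low = , undefined = )` of group ids.
#' @export
apcPartition <- function(apcResult, threshold = 0.5) {
  stopifnot(is(apcResult, "ApcResult"))
  threshold <- .assertScalar(threshold, "threshold", lower = -1, upper = 1)
  a <- apcResult@apc
  ids <- apcResult@groupIds
  list(high = ids[!is.na(a) & a > threshold],
       low = ids[!is.na(a) & a <= threshold],
       undefined = ids[is.na(a)])
}
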