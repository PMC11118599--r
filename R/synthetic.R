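# Seeded synthetic-data generators: separable labeled tables (stand-ins
# for tabular / featurized image data) and replicate-structured expression
# sets (stand-ins for L1000-style level-4 replicates and level-5
# signatures).

#' Gaussian-blob labeled table
#'
#' Class-conditional Gaussians with unit within-class covariance. Class
#' means sit at `separation / sqrt(2)` along mutually orthonormal random
#' directions, so every pair of class means is exactly `separation` apart.
#' Features are standardized to zero mean and unit variance; rows are
#' shuffled so class order carries no information. Requires `d >=
#' nClasses`.
#'
#' @param n total number of samples (split as evenly as possible across
#'   classes).
#' @param d number of features.
#' @param nClasses number of classes (default 2).
#' @param separation Euclidean distance between class means before
#'   standardization; 0 gives labels independent of features.
#' @param seed RNG seed; generation is bit-reproducible.
#' @return a [LabeledTable-class] with `params` recording the call.
#' @export
makeBlobs <- function(n, d, nClasses = 2L, separation = 4, seed = 0L) {
  n <- .assertCount(n, "n")
  d <- .assertCount(d, "d")
  nClasses <- .assertCount(nClasses, "nClasses", min = 2L)
  separation <- .assertScalar(separation, "separation", lower = 0)
  if (n < nClasses) stop("'n' must be at least 'nClasses'")
  if (d < nClasses) stop("'d' must be at least 'nClasses' for orthonormal class means")
  counts <- rep(n %/% nClasses, nClasses)
  rem <- n - sum(counts)
  if (rem > 0L) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1L
  X <- matrix(0, n, d)
  y <- integer(n)
  withSeed(seed, {
    Q <- qr.Q(qr(matrix(rnorm(d * nClasses), d, nClasses)))
    mu <- t(Q) * separation / sqrt(2)          # nClasses x d
    row <- 0L
    for (k in seq_len(nClasses)) {
      idx <- row + seq_len(counts[k])
      X[idx, ] <- matrix(rnorm(counts[k] * d), counts[k], d) +
        matrix(mu[k, ], counts[k], d, byrow = TRUE)
      y[idx] <- k - 1L
      row <- row + counts[k]
    }
    ord <- sample.int(n)
    X <- X[ord, , drop = FALSE]
    y <- y[ord]
  })
  X <- scale(X)
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  ids <- paste0("s", seq_len(n))
  rownames(X) <- ids
  new("LabeledTable", X = X, y = y, sampleIds = ids,
      labelMap = as.character(0:(nClasses - 1L)),
      params = list(generator = "blobs", n = n, d = d, nClasses = nClasses,
                    separation = separation, seed = as.integer(seed)))
}

#' @describeIn LabeledTable-class the samples x features matrix.
#' @param x a `LabeledTable`.
#' @export
features <- function(x) {
  stopifnot(is(x, "LabeledTable"))
  x@X
}

#' @describeIn LabeledTable-class 0-based integer class labels (length 0
#'   when unlabeled).
#' @export
classLabels <- function(x) {
  stopifnot(is(x, "LabeledTable"))
  x@y
}

#' @describeIn LabeledTable-class sample identifiers.
#' @export
sampleIds <- function(x) {
  stopifnot(is(x, "LabeledTable"))
  x@sampleIds
}

#' @describeIn LabeledTable-class generator / provenance parameters.
#' @export
generatorParams <- function(x) {
  stopifnot(is(x, "LabeledTable"))
  x@params
}

#' @describeIn LabeledTable-class compact summary.
#' @param object a `LabeledTable`.
#' @export
setMethod("show", "LabeledTable", function(object) {
  cat(sprintf("LabeledTable: %d samples x %d features", nrow(object@X),
              ncol(object@X)))
  if (length(object@y)) {
    cat(sprintf(" | %d classes (%s)", length(object@labelMap),
                paste(tabulate(object@y + 1L), collapse = "/")))
  }
  cat("\n")
})

#' Synthetic replicate-structured expression set
#'
#' Emulates the replicate structure of L1000-style data: each perturbation
#' group has a true signature, and each replicate profile is the group
#' signature plus independent Gaussian noise whose standard deviation is
#' drawn per replicate from Uniform(noiseSdRange). True signatures are
#' generated from a latent factor model — `nFactors` latent scores per
#' group times a shared gene-loading matrix, scaled so every gene's
#' marginal standard deviation is `signalSd` — mirroring the co-regulated,
#' effectively low-dimensional structure of real expression signatures
#' (with `nFactors = nGenes` the genes become independent). Group-level
#' (level-5-style) signatures are the per-group replicate means — a
#' declared simplification of the weighted (MODZ) aggregate used by the
#' real pipeline. Noisier groups have lower replicate concordance (APC)
#' and their signatures sit further off the signal manifold, which is what
#' makes this fixture informative for unsupervised valuation.
#'
#' @param nGroups number of perturbation groups.
#' @param repsPerGroup replicates per group (>= 2).
#' @param nGenes number of genes (default 978, the landmark panel size).
#' @param signalSd marginal standard deviation of true gene effects.
#' @param noiseSdRange `c(low, high)` of the per-replicate noise standard
#'   deviation.
#' @param nFactors latent dimensionality of the signal manifold (default
#'   32, capped at `nGenes`).
#' @param seed RNG seed; generation is bit-reproducible.
#' @return a [ReplicateExpressionSet-class] (genes x replicates assay
#'   `level4`; `colData` columns `group`, `noiseSd`; true signatures in
#'   `metadata(x)$trueSignal`).
#' @export
makeReplicateExpression <- function(nGroups, repsPerGroup = 3L, nGenes = 978L,
                                    signalSd = 1, noiseSdRange = c(0.1, 2),
                                    nFactors = 32L, seed = 0L) {
  nGroups <- .assertCount(nGroups, "nGroups")
  repsPerGroup <- .assertCount(repsPerGroup, "repsPerGroup", min = 2L)
  nGenes <- .assertCount(nGenes, "nGenes")
  signalSd <- .assertScalar(signalSd, "signalSd", lower = 0)
  if (length(noiseSdRange) != 2L) stop("'noiseSdRange' must be c(low, high)")
  low <- .assertScalar(noiseSdRange[1], "noiseSdRange[1]", lower = 0)
  high <- .assertScalar(noiseSdRange[2], "noiseSdRange[2]", lower = low)
  nFactors <- min(.assertCount(nFactors, "nFactors"), nGenes)
  nRep <- nGroups * repsPerGroup
  withSeed(seed, {
    # gene loadings with unit row norms per gene so each gene's marginal
    # signal standard deviation is signalSd
    W <- matrix(rnorm(nFactors * nGenes), nFactors, nGenes)
    W <- sweep(W, 2L, sqrt(colSums(W^2)), "/")
    Z <- matrix(rnorm(nGroups * nFactors), nGroups, nFactors)
    signal <- signalSd * (Z %*% W)
    noiseSd <- runif(nRep, low, high)
    level4 <- signal[rep(seq_len(nGroups), each = repsPerGroup), ] +
      matrix(rnorm(nRep * nGenes), nRep, nGenes) * noiseSd
  })
  groupIds <- sprintf("pert%04d", seq_len(nGroups))
  repIds <- sprintf("%s_r%d", rep(groupIds, each = repsPerGroup),
                    rep(seq_len(repsPerGroup), times = nGroups))
  geneIds <- sprintf("g%03d", seq_len(nGenes))
  assayM <- t(level4)
  dimnames(assayM) <- list(geneIds, repIds)
  rownames(signal) <- groupIds
  colnames(signal) <- geneIds
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(level4 = assayM),
    colData = S4Vectors::DataFrame(
      group = rep(groupIds, each = repsPerGroup),
      noiseSd = noiseSd, row.names = repIds),
    metadata = list(trueSignal = t(signal),
                    params = list(generator = "replicate_expression",
                                  nGroups = nGroups,
                                  repsPerGroup = repsPerGroup,
                                  nGenes = nGenes, signalSd = signalSd,
                                  noiseSdRange = c(low, high),
                                  nFactors = nFactors,
                                  seed = as.integer(seed)))
  )
  new("ReplicateExpressionSet", se)
}

#' @describeIn ReplicateExpressionSet-class genes x replicates level-4
#'   matrix.
#' @param x a `ReplicateExpressionSet`.
#' @export
level4 <- function(x) {
  stopifnot(is(x, "ReplicateExpressionSet"))
  SummarizedExperiment::assay(x, "level4")
}

#' @describeIn ReplicateExpressionSet-class genes x groups level-5-style
#'   signature matrix (per-group replicate means).
#' @export
level5 <- function(x) {
  stopifnot(is(x, "ReplicateExpressionSet"))
  M <- SummarizedExperiment::assay(x, "level4")
  g <- as.character(SummarizedExperiment::colData(x)$group)
  ids <- unique(g)
  out <- vapply(ids, function(id) {
    rowMeans(M[, g == id, drop = FALSE])
  }, numeric(nrow(M)))
  colnames(out) <- ids
  out
}

#' @describeIn ReplicateExpressionSet-class replicate-to-group map.
#' @export
replicateGroups <- function(x) {
  stopifnot(is(x, "ReplicateExpressionSet"))
  stats::setNames(as.character(SummarizedExperiment::colData(x)$group),
                  colnames(x))
}

#' @describeIn ReplicateExpressionSet-class per-replicate simulated noise
#'   standard deviations (`NULL` for non-synthetic sets).
#' @export
replicateNoiseSd <- function(x) {
  stopifnot(is(x, "ReplicateExpressionSet"))
  cd <- SummarizedExperiment::colData(x)
  if (!"noiseSd" %in% colnames(cd)) return(NULL)
  stats::setNames(cd$noiseSd, colnames(x))
}

#' @describeIn ReplicateExpressionSet-class per-group mean simulated noise
#'   standard deviation.
#' @export
groupNoiseSd <- function(x) {
  sds <- replicateNoiseSd(x)
  if (is.null(sds)) return(NULL)
  g <- replicateGroups(x)
  vapply(split(sds, g)[unique(g)], mean, numeric(1))
}

#' @describeIn ReplicateExpressionSet-class genes x groups matrix of true
#'   (noise-free) signatures, when available.
#' @export
trueSignal <- function(x) {
  stopifnot(is(x, "ReplicateExpressionSet"))
  S4Vectors::metadata(x)$trueSignal
}
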