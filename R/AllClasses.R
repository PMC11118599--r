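#' @import methods
#' @importFrom stats cor rnorm runif sd
#' @importFrom utils read.csv write.csv count.fields
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' Feed-forward differentiable model
#'
#' Container for a small fully-connected network trained by plain SGD.
#' Parameters are held as per-layer weight matrices and bias vectors; the
#' flattened parameter vector (column-major weights followed by biases,
#' layer by layer) has a fixed ordering that all gradient code shares.
#'
#' @slot weights list of weight matrices, one per layer (in-dim x out-dim).
#' @slot biases list of bias vectors, one per layer.
#' @slot activation hidden-layer activation, `"relu"` or `"identity"`.
#'   The output layer is always linear (logits / reconstruction).
#' @slot task `"classification"` (softmax + cross-entropy) or
#'   `"reconstruction"` (mean squared error over features).
#' @slot descriptor list describing the architecture (`layerSizes`,
#'   `activation`, `task`, `seed`) — sufficient to rebuild the model.
#'
#' @seealso [makeMLP()], [makeAutoencoder()], [feedForwardNet()]
#' @export
setClass("DiffModel",
  representation(
    weights = "list",
    biases = "list",
    activation = "character",
    task = "character",
    descriptor = "list"
  )
)

setValidity("DiffModel", function(object) {
  L <- length(object@weights)
  if (L < 1L) return("model needs at least one layer")
  if (length(object@biases) != L) return("weights/biases layer count mismatch")
  for (l in seq_len(L)) {
    if (ncol(object@weights[[l]]) != length(object@biases[[l]])) {
      return(sprintf("layer %d: bias length != weight columns", l))
    }
    if (l > 1L && nrow(object@weights[[l]]) != ncol(object@weights[[l - 1L]])) {
      return(sprintf("layer %d: input size != previous output size", l))
    }
  }
  if (!object@activation %in% c("relu", "identity")) {
    return("activation must be 'relu' or 'identity'")
  }
  if (!object@task %in% c("classification", "reconstruction")) {
    return("task must be 'classification' or 'reconstruction'")
  }
  TRUE
})

#' Loss specification
#'
#' @slot name `"cross_entropy"` or `"mse_reconstruction"`.
#' @slot classWeights optional non-negative per-class weight vector applied
#'   to per-sample cross-entropy terms (empty numeric = unweighted).
#'
#' @export
setClass("LossSpec",
  representation(name = "character", classWeights = "numeric")
)

setValidity("LossSpec", function(object) {
  if (!object@name %in% c("cross_entropy", "mse_reconstruction")) {
    return("unknown loss name")
  }
  w <- object@classWeights
  if (length(w)) {
    if (any(!is.finite(w)) || any(w < 0)) return("class weights must be finite and non-negative")
    if (all(w == 0)) return("class weights must not all be zero")
  }
  TRUE
})

#' Per-sample data values
#'
#' Result container shared by every valuation method in the package
#' (gradient similarity, random, leave-one-out, Shapley). For the gradient
#' similarity method, `values` is the grand mean of recorded cosine
#' similarities over iterations and runs, so every entry lies in [-1, 1].
#'
#' @slot values numeric vector, one value per source sample (possibly
#'   named by sample id; `NA` marks a sample whose value could not be
#'   computed, e.g. a degenerate leave-one-out refit).
#' @slot nRecords integer vector: number of recorded similarity snapshots
#'   per run (empty for methods without an iteration dimension).
#' @slot perIteration list of per-run matrices (samples x recorded
#'   iterations) of raw similarities; empty unless recording was requested.
#' @slot method name of the valuation method that produced the values.
#' @slot params list snapshot of the configuration used.
#' @slot extra method-specific diagnostics (e.g. `converged` for the
#'   truncated Monte-Carlo Shapley estimator, final parameter vectors for
#'   SGD runs).
#'
#' @export
setClass("DataValues",
  representation(
    values = "numeric",
    nRecords = "integer",
    perIteration = "list",
    method = "character",
    params = "list",
    extra = "list"
  ),
  prototype(nRecords = integer(), perIteration = list(),
            method = "unknown", params = list(), extra = list())
)

setValidity("DataValues", function(object) {
  for (m in object@perIteration) {
    if (!is.matrix(m) || nrow(m) != length(object@values)) {
      return("perIteration matrices must have one row per sample")
    }
  }
  if (length(object@nRecords) && any(object@nRecords < 0L)) {
    return("nRecords must be non-negative")
  }
  TRUE
})

#' Labeled feature table
#'
#' A samples x features numeric matrix with optional integer class labels
#' (coded 0..K-1) and the map back to the original label strings.
#'
#' @slot X numeric matrix, samples in rows.
#' @slot y integer vector of class codes (length 0 when unlabeled).
#' @slot sampleIds character vector of row identifiers.
#' @slot labelMap character vector: `labelMap[code + 1]` is the original
#'   label for `code`.
#' @slot params generator / provenance parameters.
#'
#' @export
setClass("LabeledTable",
  representation(
    X = "matrix",
    y = "integer",
    sampleIds = "character",
    labelMap = "character",
    params = "list"
  ),
  prototype(y = integer(), labelMap = character(), params = list())
)

setValidity("LabeledTable", function(object) {
  if (!is.numeric(object@X)) return("X must be numeric")
  if (length(object@sampleIds) != nrow(object@X)) {
    return("sampleIds length must equal number of rows")
  }
  if (length(object@y) && length(object@y) != nrow(object@X)) {
    return("labels length must equal number of rows")
  }
  if (anyNA(object@X)) return("X must not contain missing values")
  TRUE
})

#' Filter-and-retrain performance curve
#'
#' Test-set performance as a function of the fraction of source data
#' removed, removing either the lowest- or the highest-valued samples.
#'
#' @slot fractions strictly increasing fractions in [0, 1), first entry 0.
#' @slot direction `"remove_lowest"` or `"remove_highest"`.
#' @slot scores matrix of metric values, replicate fits in rows, one
#'   column per fraction.
#' @slot metricName metric used for scoring the held-out test set.
#'
#' @export
setClass("FilterCurve",
  representation(
    fractions = "numeric",
    direction = "character",
    scores = "matrix",
    metricName = "character"
  )
)

setValidity("FilterCurve", function(object) {
  f <- object@fractions
  if (length(f) == 0L || f[1] != 0) return("fractions must start at 0")
  if (any(diff(f) <= 0)) return("fractions must be strictly increasing")
  if (any(f >= 1)) return("fractions must be < 1")
  if (ncol(object@scores) != length(f)) {
    return("scores must have one column per fraction")
  }
  if (!object@direction %in% c("remove_lowest", "remove_highest")) {
    return("direction must be remove_lowest or remove_highest")
  }
  if (any(!is.finite(object@scores))) return("scores must be finite")
  TRUE
})

#' Replicate-level average Pearson correlation result
#'
#' @slot groupIds perturbation-group identifiers.
#' @slot apc per-group mean pairwise Pearson correlation of replicate
#'   profiles (`NA` for groups with fewer than two replicates).
#' @slot nReplicates per-group replicate counts.
#' @slot nDroppedPairs per-group count of replicate pairs excluded because
#'   a constant profile made the correlation undefined.
#'
#' @export
setClass("ApcResult",
  representation(
    groupIds = "character",
    apc = "numeric",
    nReplicates = "integer",
    nDroppedPairs = "integer"
  )
)

setValidity("ApcResult", function(object) {
  n <- length(object@groupIds)
  if (length(object@apc) != n || length(object@nReplicates) != n ||
      length(object@nDroppedPairs) != n) {
    return("all slots must have one entry per group")
  }
  ok <- !is.na(object@apc)
  if (any(object@apc[ok] < -1 - 1e-12 | object@apc[ok] > 1 + 1e-12)) {
    return("apc values must lie in [-1, 1]")
  }
  TRUE
})

#' Replicate-structured expression set
#'
#' A \linkS4class{SummarizedExperiment} holding a level-4-style replicate
#' expression matrix (genes in rows, replicate profiles in columns) with
#' `colData` columns `group` (perturbation group of each replicate) and,
#' for synthetic sets, `noiseSd` (the replicate's simulated noise standard
#' deviation). The group-level (level-5-style) signature matrix is the
#' per-group replicate mean, available through [level5()].
#'
#' @export
setClass("ReplicateExpressionSet", contains = "SummarizedExperiment")

setValidity("ReplicateExpressionSet", function(object) {
  if (!"group" %in% colnames(SummarizedExperiment::colData(object))) {
    return("colData must contain a 'group' column")
  }
  if (!"level4" %in% SummarizedExperiment::assayNames(object)) {
    return("assay 'level4' is required")
  }
  TRUE
})

#' Retrainable learner
#'
#' The fit/score contract used by the leave-one-out and Shapley baselines
#' and by [filterAndRetrain()]: `fitFun(X, y, seed)` returns a fitted
#' state, `predictFun(state, X)` returns predictions, and `nullFun()`
#' returns the state of the uninformed learner (used as the empty-set
#' baseline for Shapley values).
#'
#' @slot name learner label.
#' @slot fitFun function(X, y, seed) -> state.
#' @slot predictFun function(state, X) -> numeric predictions (vector, or
#'   matrix of class probabilities).
#' @slot nullFun function() -> state of the learner fit on no data.
#'
#' @seealso [meanLearner()], [mlpLearner()], [autoencoderLearner()]
#' @export
setClass("Learner",
  representation(
    name = "character",
    fitFun = "function",
    predictFun = "function",
    nullFun = "function"
  )
)
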