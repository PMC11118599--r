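#' Configuration for a gradient-similarity valuation run
#'
#' @param learningRate SGD step size (alpha) for the target-set updates.
#' @param nIterations number of SGD iterations per run.
#' @param targetBatchSize target mini-batch size (R).
#' @param similarityPeriod record similarities every T-th iteration
#'   (default 1 = every iteration). Recording cost scales as 1/T.
#' @param nRuns number of independent runs (fresh initialization and batch
#'   order per run); values are averaged over all recorded similarities of
#'   all runs.
#' @param baseSeed seed of the first run; run r uses `baseSeed + r - 1`.
#' @param similarity similarity criterion; `"cosine"` is the validated
#'   default, `"dot"` and `"euclidean"` are provided for experimentation.
#' @param classBalance weight target-gradient class contributions inversely
#'   to class frequency (computed once from the full target set), so an
#'   imbalanced target does not bias values toward its majority class.
#' @param pretrainEpochs epochs of target-only SGD before any similarity is
#'   recorded (0 = none).
#' @param recordPerIteration keep the full samples x recorded-iterations
#'   similarity matrix for each run.
#' @param gradientMethod `"fast"` (vectorized) or `"loop"` (explicit
#'   per-sample gradients); both give identical similarities.
#' @return a named list of validated settings.
#' @export
dvgsConfig <- function(learningRate = 0.05, nIterations = 500L,
                       targetBatchSize = 50L, similarityPeriod = 1L,
                       nRuns = 1L, baseSeed = 1L,
                       similarity = c("cosine", "dot", "euclidean"),
                       classBalance = FALSE, pretrainEpochs = 0L,
                       recordPerIteration = FALSE,
                       gradientMethod = c("fast", "loop")) {
  cfg <- list(
    learningRate = .assertScalar(learningRate, "learningRate", lower = 1e-12),
    nIterations = .assertCount(nIterations, "nIterations"),
    targetBatchSize = .assertCount(targetBatchSize, "targetBatchSize"),
    similarityPeriod = .assertCount(similarityPeriod, "similarityPeriod"),
    nRuns = .assertCount(nRuns, "nRuns"),
    baseSeed = .assertCount(baseSeed, "baseSeed", min = 0L),
    similarity = match.arg(similarity),
    classBalance = isTRUE(classBalance),
    pretrainEpochs = .assertCount(pretrainEpochs, "pretrainEpochs", min = 0L),
    recordPerIteration = isTRUE(recordPerIteration),
    gradientMethod = match.arg(gradientMethod)
  )
  if (cfg$similarityPeriod > cfg$nIterations) {
    stop("'similarityPeriod' must not exceed 'nIterations'")
  }
  cfg
}

# Epoch-wise mini-batch index stream: without replacement within an epoch,
# reshuffled each epoch. Consumes the current RNG stream.
.nextBatch <- function(state, n, size) {
  if (is.null(state$order) || state$pos + size - 1L > n) {
    state$order <- sample.int(n)
    state$pos <- 1L
  }
  idx <- state$order[state$pos:(state$pos + size - 1L)]
  state$pos <- state$pos + size
  list(idx = idx, state = state)
}

.oneDvgsRun <- function(modelFactory, src, tgt, cfg, seed, verbose) {
  model <- modelFactory(seed)
  loss <- .defaultLoss(model)
  tgtLoss <- loss
  if (model@task == "classification" && cfg$classBalance) {
    nC <- ncol(model@weights[[length(model@weights)]])
    tgtLoss@classWeights <- balancedClassWeights(tgt$y, nC)
  }
  nT <- nrow(tgt$X)
  R <- min(cfg$targetBatchSize, nT)
  nRec <- cfg$nIterations %/% cfg$similarityPeriod
  sims <- matrix(NA_real_, nrow(src$X), nRec)
  rec <- 0L
  withSeed(seed, {
    state <- list(order = NULL, pos = 1L)
    if (cfg$pretrainEpochs > 0L) {
      for (e in seq_len(cfg$pretrainEpochs)) {
        for (b in seq_len(max(1L, nT %/% R))) {
          nb <- .nextBatch(state, nT, R)
          state <- nb$state
          bX <- tgt$X[nb$idx, , drop = FALSE]
          by <- if (is.null(tgt$y)) NULL else tgt$y[nb$idx]
          g <- .batchGradList(model, bX, by, tgtLoss)
          model <- .sgdStep(model, g, cfg$learningRate)
        }
      }
    }
    for (i in seq_len(cfg$nIterations)) {
      nb <- .nextBatch(state, nT, R)
      state <- nb$state
      bX <- tgt$X[nb$idx, , drop = FALSE]
      by <- if (is.null(tgt$y)) NULL else tgt$y[nb$idx]
      bl <- mean(.perSampleLossCore(model, bX, by, tgtLoss))
      if (!is.finite(bl)) {
        stop(sprintf("optimization diverged (non-finite target loss) at iteration %d", i))
      }
      g <- .batchGradList(model, bX, by, tgtLoss)
      if (i %% cfg$similarityPeriod == 0L) {
        rec <- rec + 1L
        gFlat <- .flattenGrad(g)
        sims[, rec] <- gradientSimilarities(
          model, src$X, src$y, gFlat, loss = loss,
          similarity = cfg$similarity, method = cfg$gradientMethod)
        if (verbose) {
          message(sprintf("iter %d | target loss %.5f | recorded snapshot %d",
                          i, bl, rec))
        }
      } else if (verbose && i %% 100L == 0L) {
        message(sprintf("iter %d | target loss %.5f", i, bl))
      }
      model <- .sgdStep(model, g, cfg$learningRate)
    }
  })
  list(sims = sims[, seq_len(rec), drop = FALSE], nRecords = rec,
       finalParameters = modelParameters(model))
}

#' Data valuation with gradient similarity
#'
#' Runs SGD on the target set and, every `similarityPeriod`-th iteration
#' (before the parameter update), records the cosine similarity between
#' each source sample's loss gradient and the target mini-batch gradient.
#' A sample's data value is the mean of its recorded similarities over all
#' iterations and runs; samples whose gradients consistently align with
#' the target's descent direction get values near +1, samples that oppose
#' it (e.g. mislabeled ones) get negative values.
#'
#' @param source dataset to be valued: a [LabeledTable-class], a numeric
#'   matrix (samples x features), or `list(X, y)` with 0-based labels.
#' @param target dataset defining the valuation objective, same formats;
#'   for reconstruction tasks the targets are the inputs themselves.
#' @param modelFactory `function(seed)` returning a fresh
#'   [DiffModel-class]; called once per run. If `NULL`, a default
#'   architecture is built from `task`: a 2-layer MLP (hidden width 100)
#'   for classification, a 2-layer-encoder/decoder autoencoder (32 latent)
#'   for reconstruction.
#' @param task used only when `modelFactory` is `NULL`.
#' @param config a [dvgsConfig()] list.
#' @param hiddenDim,latentDim architecture settings for the default
#'   factories.
#' @param verbose log iteration, target loss and recording events.
#' @return a [DataValues-class] with one value per source sample.
#' @examples
#' tab <- makeBlobs(n = 120, d = 5, separation = 4, seed = 1)
#' dv <- runDVGS(tab, tab, config = dvgsConfig(nIterations = 20, baseSeed = 1))
#' summary(dataValues(dv))
#' @export
runDVGS <- function(source, target, modelFactory = NULL,
                    task = c("classification", "reconstruction"),
                    config = dvgsConfig(), hiddenDim = 100L, latentDim = 32L,
                    verbose = FALSE) {
  src <- .asXY(source, "source")
  tgt <- .asXY(target, "target")
  if (nrow(src$X) == 0L || nrow(tgt$X) == 0L) {
    stop("source and target must be non-empty")
  }
  if (ncol(src$X) != ncol(tgt$X)) {
    stop("source and target feature dimensionalities differ")
  }
  if (is.null(modelFactory)) {
    task <- match.arg(task)
    d <- ncol(src$X)
    modelFactory <- if (task == "classification") {
      nC <- max(2L, length(unique(c(src$y, tgt$y))))
      function(seed) makeMLP(d, hiddenDim = hiddenDim, nClasses = nC,
                             seed = seed)
    } else {
      function(seed) makeAutoencoder(d, latentDim = latentDim, seed = seed)
    }
  }
  runs <- lapply(seq_len(config$nRuns), function(r) {
    .oneDvgsRun(modelFactory, src, tgt, config,
                seed = config$baseSeed + r - 1L, verbose = verbose)
  })
  totals <- numeric(nrow(src$X))
  nRecs <- integer(config$nRuns)
  perIter <- list()
  for (r in seq_along(runs)) {
    totals <- totals + rowSums(runs[[r]]$sims)
    nRecs[r] <- runs[[r]]$nRecords
    if (config$recordPerIteration) perIter[[r]] <- runs[[r]]$sims
  }
  vals <- totals / sum(nRecs)
  names(vals) <- src$ids
  new("DataValues", values = vals, nRecords = nRecs, perIteration = perIter,
      method = "dvgs",
      params = config,
      extra = list(finalParameters = lapply(runs, `[[`, "finalParameters")))
}

#' Pool data values across independent runs
#'
#' Element-wise mean of per-run values weighted by each run's number of
#' recorded snapshots, so the result equals the grand mean over all
#' recorded similarities of all runs.
#'
#' @param perRun list of [DataValues-class] objects over the same source
#'   set (each may itself summarize several runs).
#' @return a single pooled [DataValues-class].
#' @export
aggregateRuns <- function(perRun) {
  if (!length(perRun)) stop("need at least one run")
  n <- length(perRun[[1]]@values)
  for (dv in perRun) {
    if (length(dv@values) != n) stop("runs cover different source sizes")
  }
  wts <- vapply(perRun, function(dv) {
    if (length(dv@nRecords)) sum(dv@nRecords) else 1L
  }, numeric(1))
  vals <- numeric(n)
  for (i in seq_along(perRun)) vals <- vals + wts[i] * perRun[[i]]@values
  vals <- vals / sum(wts)
  names(vals) <- names(perRun[[1]]@values)
  new("DataValues", values = vals,
      nRecords = as.integer(unlist(lapply(perRun, function(dv) {
        if (length(dv@nRecords)) dv@nRecords else 1L
      }))),
      perIteration = do.call(c, lapply(perRun, function(dv) dv@perIteration)),
      method = perRun[[1]]@method, params = perRun[[1]]@params,
      extra = list())
}

#' @describeIn DataValues-class extract the per-sample value vector.
#' @param x a `DataValues`.
#' @export
dataValues <- function(x) {
  stopifnot(is(x, "DataValues"))
  x@values
}

#' @describeIn DataValues-class number of independent runs pooled.
#' @export
nRuns <- function(x) {
  stopifnot(is(x, "DataValues"))
  max(1L, length(x@nRecords))
}

#' @describeIn DataValues-class name of the method that produced the values.
#' @export
valuationMethod <- function(x) {
  stopifnot(is(x, "DataValues"))
  x@method
}

#' @describeIn DataValues-class per-run samples x recorded-iterations
#'   similarity matrices (empty list unless recording was requested).
#' @export
perIteration <- function(x) {
  stopifnot(is(x, "DataValues"))
  x@perIteration
}

#' @describeIn DataValues-class compact summary.
#' @param object a `DataValues`.
#' @export
setMethod("show", "DataValues", function(object) {
  v <- object@values
  cat(sprintf("DataValues: %d samples | method=%s | runs=%d\n",
              length(v), object@method, max(1L, length(object@nRecords))))
  if (length(v)) {
    cat(sprintf("  values: min %.4f | median %.4f | max %.4f | NA %d\n",
                min(v, na.rm = TRUE), stats::median(v, na.rm = TRUE),
                max(v, na.rm = TRUE), sum(is.na(v))))
  }
})
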