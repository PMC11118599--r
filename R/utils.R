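# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.assertCount <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min) {
    stop(sprintf("'%s' must be an integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}

.assertScalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("'%s' must be a finite scalar in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  as.numeric(x)
}

# Accept a LabeledTable, a numeric matrix, or a list(X, y); return list(X, y,
# ids) with X a samples x features matrix and y a 0-based integer vector or
# NULL.
.asXY <- function(data, name = "data") {
  if (is(data, "LabeledTable")) {
    y <- if (length(data@y)) data@y else NULL
    return(list(X = data@X, y = y, ids = data@sampleIds))
  }
  if (is.matrix(data)) {
    ids <- rownames(data)
    if (is.null(ids)) ids <- paste0("s", seq_len(nrow(data)))
    return(list(X = data, y = NULL, ids = ids))
  }
  if (is.list(data) && !is.null(data$X)) {
    X <- as.matrix(data$X)
    ids <- rownames(X)
    if (is.null(ids)) ids <- paste0("s", seq_len(nrow(X)))
    y <- data$y
    if (!is.null(y)) y <- as.integer(y)
    return(list(X = X, y = y, ids = ids))
  }
  stop(sprintf("'%s' must be a LabeledTable, matrix, or list(X, y)", name),
       call. = FALSE)
}

.valuesVector <- function(values) {
  if (is(values, "DataValues")) values@values else as.numeric(values)
}

# Mid-rank (Mann-Whitney) AUROC of `scores` for predicting `positive`.
.aurocRank <- function(scores, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) {
    stop("AUROC undefined: both classes must be present", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
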