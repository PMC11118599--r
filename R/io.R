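# CSV / YAML interchange: labeled tables, value tables, run configs.

#' Read a labeled feature table from CSV
#'
#' Reads a rectangular CSV with a header row. Feature columns must be
#' numeric; the optional label column is coded to contiguous 0-based
#' integers by lexicographic order of the distinct labels, and the code
#' map is retained. Row order is preserved. Sample identity is taken from
#' `idColumn` when given and is positional (`s1..sn`) otherwise.
#'
#' @param path CSV file path.
#' @param labelColumn name of the label column, or `NULL` for an
#'   unlabeled table.
#' @param idColumn optional name of a sample-id column; a column named
#'   `sample_id` (as written by [writeLabeledTable()]) is used
#'   automatically.
#' @return a [LabeledTable-class].
#' @export
readLabeledTable <- function(path, labelColumn = NULL, idColumn = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  fields <- count.fields(path, sep = ",", quote = "\"")
  if (length(unique(fields)) > 1L) {
    bad <- which(fields != fields[1])[1]
    stop(sprintf("ragged CSV: row %d has %d fields, expected %d",
                 bad, fields[bad], fields[1]))
  }
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (is.null(idColumn) && "sample_id" %in% names(df)) idColumn <- "sample_id"
  ids <- if (!is.null(idColumn)) {
    if (!idColumn %in% names(df)) stop(sprintf("id column '%s' not found", idColumn))
    as.character(df[[idColumn]])
  } else paste0("s", seq_len(nrow(df)))
  y <- integer()
  labelMap <- character()
  if (!is.null(labelColumn)) {
    if (!labelColumn %in% names(df)) {
      stop(sprintf("label column '%s' not found", labelColumn))
    }
    raw <- as.character(df[[labelColumn]])
    labelMap <- sort(unique(raw))
    y <- match(raw, labelMap) - 1L
  }
  featNames <- setdiff(names(df), c(labelColumn, idColumn))
  X <- matrix(NA_real_, nrow(df), length(featNames),
              dimnames = list(ids, featNames))
  for (j in seq_along(featNames)) {
    col <- df[[featNames[j]]]
    num <- suppressWarnings(as.numeric(col))
    if (anyNA(num)) {
      bad <- which(is.na(num))[1]
      stop(sprintf("non-numeric feature value at row %d, column '%s'",
                   bad, featNames[j]))
    }
    X[, j] <- num
  }
  new("LabeledTable", X = X, y = y, sampleIds = ids, labelMap = labelMap,
      params = list(source = path, labelColumn = labelColumn))
}

#' Write a labeled table to CSV
#'
#' Inverse of [readLabeledTable()]: writes `sample_id`, the feature
#' columns at full precision, and (when present) a `label` column with
#' the original label strings.
#'
#' @param table a [LabeledTable-class].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeLabeledTable <- function(table, path) {
  stopifnot(is(table, "LabeledTable"))
  df <- data.frame(sample_id = table@sampleIds, check.names = FALSE)
  X <- table@X
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  for (j in seq_len(ncol(X))) df[[colnames(X)[j]]] <- .fullPrec(X[, j])
  if (length(table@y)) df$label <- table@labelMap[table@y + 1L]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Full-precision decimal rendering so numeric round trips are bit exact.
.fullPrec <- function(x) {
  vapply(x, function(v) sprintf("%.17g", v), character(1))
}

#' Write data values to CSV
#'
#' Columns `sample_id`, `value` (full precision, round-trip exact),
#' `method`, `n_runs`, plus `converged` when the method reports a
#' convergence flag (Shapley).
#'
#' @param values a [DataValues-class].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeValues <- function(values, path) {
  stopifnot(is(values, "DataValues"))
  v <- values@values
  if (length(v) == 0L) {
    writeLines("sample_id,value,method,n_runs", path)
    return(invisible(path))
  }
  ids <- names(v)
  if (is.null(ids)) ids <- paste0("s", seq_along(v))
  df <- data.frame(sample_id = ids, value = .fullPrec(v),
                   method = rep(values@method, length(v)),
                   n_runs = rep(max(1L, length(values@nRecords)), length(v)))
  if (!is.null(values@extra$converged)) {
    df$converged <- rep(values@extra$converged, length(v))
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read data values from CSV
#' @param path a CSV written by [writeValues()].
#' @return a [DataValues-class].
#' @export
readValues <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.numeric(df$value)
  names(vals) <- df$sample_id
  extra <- list()
  if ("converged" %in% names(df) && nrow(df)) {
    extra$converged <- as.logical(df$converged[1])
  }
  new("DataValues", values = vals,
      method = if (nrow(df)) df$method[1] else "unknown",
      nRecords = integer(), extra = extra)
}

#' Write the per-iteration similarity record
#'
#' One CSV per run: samples in rows, recorded iterations in columns.
#'
#' @param values a [DataValues-class] produced with
#'   `recordPerIteration = TRUE`.
#' @param path output path; for multi-run values, `_run<k>` is inserted
#'   before the extension.
#' @return the written paths, invisibly.
#' @export
writePerIteration <- function(values, path) {
  stopifnot(is(values, "DataValues"))
  mats <- values@perIteration
  if (!length(mats)) stop("no per-iteration record present")
  paths <- character(length(mats))
  for (r in seq_along(mats)) {
    p <- if (length(mats) == 1L) path else
      sub("(\\.[^.]*)?$", sprintf("_run%d\\1", r), path)
    m <- mats[[r]]
    df <- data.frame(sample_id = names(values@values))
    for (j in seq_len(ncol(m))) df[[paste0("iter", j)]] <- .fullPrec(m[, j])
    write.csv(df, p, row.names = FALSE, quote = FALSE)
    paths[r] <- p
  }
  invisible(paths)
}

#' Read / write a valuation run configuration
#'
#' Run configs are plain YAML mappings mirroring the arguments of
#' [dvgsConfig()] / [shapleyConfig()] plus method, task, dataset paths and
#' output paths; a saved config re-runs to identical results given its
#' seeds.
#'
#' @param config named list to save.
#' @param path YAML file path.
#' @return `writeRunConfig`: the path, invisibly; `readRunConfig`: the
#'   named list.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  yaml::read_yaml(path)
}
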