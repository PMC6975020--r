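.formatError <- function(msg, line = NULL) {
  if (!is.null(line)) msg <- sprintf("%s (line %d)", msg, line)
  stop(errorCondition(msg, class = c("steadyABC_format_error", "error")))
}

#' Read and write undirected networks as edge lists
#'
#' The edge-list format is TSV with one edge per line:
#' `source<TAB>target<TAB>sign`, sign being `+` (activation) or `-`
#' (inhibition). A header line is optional and detected by a
#' non-sign third column. Parsing is strict: malformed lines, unknown
#' signs, self-loops and duplicate edges are errors naming the offending
#' line.
#'
#' @param path file path.
#' @return `readEdgeList()`: an [UndirectedGRN-class] with nodes in order
#'   of first appearance; `writeEdgeList()`: the path, invisibly.
#' @export
readEdgeList <- function(path) {
  if (!file.exists(path)) .formatError(sprintf("no such file: %s", path))
  lines <- readLines(path)
  start <- 1L
  if (length(lines)) {
    f <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    if (length(f) >= 3 && !f[3] %in% .validSign) start <- 2L
  }
  from <- character(); to <- character(); sign <- character()
  for (i in seq_along(lines)) {
    if (i < start || !nzchar(trimws(lines[i]))) next
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 3) {
      .formatError(sprintf("expected 3 tab-separated fields, got %d",
                           length(f)), i)
    }
    if (!f[3] %in% .validSign) {
      .formatError(sprintf("unknown sign symbol '%s'", f[3]), i)
    }
    if (f[1] == f[2]) .formatError("self-loop", i)
    if (any(unorderedKey(f[1], f[2]) == unorderedKey(from, to))) {
      .formatError(sprintf("duplicate edge %s-%s", f[1], f[2]), i)
    }
    from <- c(from, f[1]); to <- c(to, f[2]); sign <- c(sign, f[3])
  }
  undirectedGRN(edges = data.frame(from = from, to = to, sign = sign,
                                   stringsAsFactors = FALSE))
}

#' @rdname readEdgeList
#' @param grn an [UndirectedGRN-class] or [DirectedGRN-class].
#' @param header write a header line.
#' @export
writeEdgeList <- function(grn, path, header = TRUE) {
  e <- edgeTable(grn)
  lines <- character()
  if (header) lines <- "source\ttarget\tsign"
  lines <- c(lines, sprintf("%s\t%s\t%s", e$from, e$to, e$sign))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write observed per-node vectors
#'
#' Two-column TSV `node<TAB>value`; an optional header is detected by a
#' non-numeric second column.
#'
#' @param path file path.
#' @return `readObservedVector()`: named numeric vector.
#' @export
readObservedVector <- function(path) {
  if (!file.exists(path)) .formatError(sprintf("no such file: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  start <- 1L
  if (length(lines)) {
    f <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    if (length(f) >= 2 && is.na(suppressWarnings(as.numeric(f[2])))) {
      start <- 2L
    }
  }
  nodes <- character(); values <- numeric()
  for (i in seq_along(lines)) {
    if (i < start) next
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 2) {
      .formatError(sprintf("expected 2 tab-separated fields, got %d",
                           length(f)), i)
    }
    v <- suppressWarnings(as.numeric(f[2]))
    if (is.na(v)) .formatError(sprintf("non-numeric value '%s'", f[2]), i)
    if (f[1] %in% nodes) .formatError(sprintf("duplicate node '%s'", f[1]), i)
    nodes <- c(nodes, f[1]); values <- c(values, v)
  }
  setNames(values, nodes)
}

#' @rdname readObservedVector
#' @param v named numeric vector.
#' @export
writeObservedVector <- function(v, path) {
  writeLines(c("node\tvalue",
               sprintf("%s\t%.17g", names(v), unname(v))), path)
  invisible(path)
}

#' Read an expression table from TSV/CSV
#'
#' Genes in rows, first column the gene identifier, header line the sample
#' labels. The separator is taken from the file extension (`.csv` comma,
#' otherwise tab).
#'
#' @param path file path.
#' @param conditions optional sample-to-condition map: a named character
#'   vector or the path of a two-column TSV `sample<TAB>condition`.
#' @return An [expressionTable()] `SummarizedExperiment`.
#' @export
readExpressionTable <- function(path, conditions = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  if (!is.numeric(m)) {
    .formatError("expression values must be numeric")
  }
  if (is.character(conditions) && length(conditions) == 1 &&
      file.exists(conditions)) {
    cm <- utils::read.table(conditions, header = FALSE, sep = "\t",
                            stringsAsFactors = FALSE)
    conditions <- setNames(cm[[2]], cm[[1]])
  }
  if (!is.null(names(conditions))) conditions <- conditions[colnames(m)]
  expressionTable(m, conditions)
}

#' @rdname readExpressionTable
#' @param table an [expressionTable()].
#' @export
writeExpressionTable <- function(table, path) {
  m <- .abundance(table)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  header <- paste(c("gene", colnames(m)), collapse = sep)
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], sprintf("%.17g", m[i, ])), collapse = sep)
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a single-cell style CSV of observations
#'
#' Comma-separated, a header row of measured component names, one row per
#' observation (cell). Returns the observations-by-components matrix to be
#' condensed with [averageObservations()].
#'
#' @param path file path.
#' @return Numeric matrix, observations in rows.
#' @export
readSingleCellCSV <- function(path) {
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                        stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(df, c(1, 2), as.numeric))),
                 arr.ind = TRUE)
    .formatError(sprintf("non-numeric cell at row %d, column %d",
                         bad[1, 1], bad[1, 2]))
  }
  m
}

#' Write an ABC result to disk
#'
#' Writes `<prefix>.json` (full provenance: resolved configuration,
#' candidate counts, realized threshold, posteriors, accepted candidates)
#' and `<prefix>.tsv`, an edge list `source target sign posterior` with
#' every link written in its majority direction and the posterior of that
#' direction. Field order is deterministic.
#'
#' @param result an [ABCResult-class].
#' @param prefix output path prefix.
#' @param dot also write `<prefix>.dot` (Graphviz; solid arrows for
#'   activation, dashed for inhibition).
#' @return Invisibly, the paths written.
#' @export
writeABCResult <- function(result, prefix, dot = FALSE) {
  stopifnot(is(result, "ABCResult"))
  p <- result@posteriors
  fwd <- p$posterior >= 0.5
  tsv <- data.frame(
    source = ifelse(fwd, p$from, p$to),
    target = ifelse(fwd, p$to, p$from),
    sign = p$sign,
    posterior = ifelse(fwd, p$posterior, 1 - p$posterior))
  tsvPath <- paste0(prefix, ".tsv")
  writeLines(c("source\ttarget\tsign\tposterior",
               sprintf("%s\t%s\t%s\t%.6g", tsv$source, tsv$target,
                       tsv$sign, tsv$posterior)), tsvPath)
  diag <- result@diagnostics
  diag$acceptedOrientationTally <- as.list(diag$acceptedOrientationTally)
  jsonPath <- paste0(prefix, ".json")
  jsonlite::write_json(list(
    network = list(nodes = nodeNames(result@network),
                   edges = edgeTable(result@network)),
    config = result@config,
    totalCandidates = result@totalCandidates,
    threshold = result@threshold,
    acceptanceFraction = result@acceptanceFraction,
    posteriors = p,
    accepted = result@accepted,
    diagnostics = diag),
    jsonPath, auto_unbox = TRUE, digits = NA, null = "null")
  paths <- c(jsonPath, tsvPath)
  if (dot) {
    dotPath <- paste0(prefix, ".dot")
    style <- ifelse(tsv$sign == "+", "solid", "dashed")
    writeLines(c("digraph GRN {",
                 sprintf('  "%s" -> "%s" [style=%s, label="%.2f"];',
                         tsv$source, tsv$target, style, tsv$posterior),
                 "}"), dotPath)
    paths <- c(paths, dotPath)
  }
  invisible(paths)
}

#' Serialize and restore run configurations
#'
#' A run configuration is a flat named list of stage parameters (solver
#' step/tolerance/maximum time, beta range, perturbation subset size,
#' acyclic filter, correlation threshold, rejection settings, pseudocount,
#' seed, paths). The YAML round-trip is lossless so any result can be
#' regenerated from the stored configuration.
#'
#' @param config named list.
#' @param path YAML file path.
#' @return `readRunConfig()`: the configuration list.
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

#' Direction inference from averaged single-cell style data
#'
#' Reproduces the averaged-data validation protocol: a single-cell style
#' CSV (observations by components) is condensed into one scaled average
#' value per component, which serves as the observed vector for ABC over
#' the supplied consensus undirected skeleton. Returns the posterior table
#' with the probability (in percent) of each link pointing in its listed
#' direction.
#'
#' @param observations matrix or path of a single-cell style CSV
#'   (see [readSingleCellCSV()]).
#' @param skeleton an [UndirectedGRN-class] or the path of an edge list.
#' @param ... passed to [runABC()].
#' @return List with `result` (the [ABCResult-class]) and `table`, a
#'   data.frame `source`, `target`, `posteriorPercent` for each link in
#'   its canonical direction.
#' @export
validateDirections <- function(observations, skeleton, ...) {
  if (is.character(observations)) {
    observations <- readSingleCellCSV(observations)
  }
  if (is.character(skeleton)) skeleton <- readEdgeList(skeleton)
  observed <- averageObservations(observations)
  res <- runABC(skeleton, observed[nodeNames(skeleton)], ...)
  p <- res@posteriors
  list(result = res,
       table = data.frame(source = p$from, target = p$to,
                          posteriorPercent = 100 * p$posterior))
}
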