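#' Build an expression table container
#'
#' Wraps a genes-by-samples abundance matrix (TPM-like or LFQ-like,
#' non-negative) and its sample-to-condition map in a
#' [SummarizedExperiment::SummarizedExperiment-class] with assay
#' `"abundance"` and a `condition` column in `colData`.
#'
#' @param values numeric matrix, genes in rows (rownames required),
#'   samples in columns (colnames required); no missing values.
#' @param conditions character vector mapping each sample to a condition
#'   name, or `NULL`.
#' @return A `SummarizedExperiment`.
#' @export
expressionTable <- function(values, conditions = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop(errorCondition("values need gene rownames and sample colnames",
                        class = c("steadyABC_data_error", "error")))
  }
  if (anyNA(values) || any(!is.finite(values)) || any(values < 0)) {
    stop(errorCondition("abundances must be finite and non-negative",
                        class = c("steadyABC_data_error", "error")))
  }
  if (ncol(values) < 2) {
    stop(errorCondition("need at least 2 samples",
                        class = c("steadyABC_data_error", "error")))
  }
  cd <- S4Vectors::DataFrame(row.names = colnames(values))
  if (!is.null(conditions)) {
    if (length(conditions) != ncol(values)) {
      stop(errorCondition("one condition per sample required",
                          class = c("steadyABC_data_error", "error")))
    }
    cd$condition <- as.character(conditions)
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = values), colData = cd)
}

.abundance <- function(table) {
  if (is(table, "SummarizedExperiment")) {
    SummarizedExperiment::assay(table, "abundance")
  } else {
    as.matrix(table)
  }
}

.dropConstantGenes <- function(m) {
  keep <- apply(m, 1, function(r) var(r) > 0)
  if (any(!keep)) {
    warning(sprintf("excluding %d constant gene(s) with undefined correlation: %s",
                    sum(!keep), paste(rownames(m)[!keep], collapse = ", ")),
            call. = FALSE)
  }
  m[keep, , drop = FALSE]
}

#' Pearson correlation matrix across samples
#'
#' Correlates every pair of genes across samples. Genes with zero sample
#' variance have no defined correlation and are excluded with a warning.
#'
#' @param table an [expressionTable()] `SummarizedExperiment` or a
#'   genes-by-samples matrix.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pearsonCorrelationMatrix <- function(table) {
  m <- .dropConstantGenes(.abundance(table))
  cor(t(m), method = "pearson")
}

#' Partial correlation matrix across samples
#'
#' Partial correlations quantify the association of two genes after
#' conditioning on all others, discriminating direct from indirect links.
#' They are computed from the inverse correlation matrix
#' \eqn{\Omega = R^{-1}} as
#' \eqn{pcor_{ij} = -\Omega_{ij} / \sqrt{\Omega_{ii}\Omega_{jj}}}. When
#' the correlation matrix is numerically singular (typical when samples
#' are fewer than genes) it is first shrunk toward the identity,
#' \eqn{R_\lambda = (1-\lambda) R + \lambda I}, with the analytic
#' Schafer-Strimmer intensity estimated from the data; the applied
#' intensity is reported via `message()` and as attribute `"shrinkage"`.
#'
#' @inheritParams pearsonCorrelationMatrix
#' @return Symmetric matrix of partial correlations with unit diagonal.
#' @export
partialCorrelationMatrix <- function(table) {
  m <- .dropConstantGenes(.abundance(table))
  if (nrow(m) < 2) {
    stop(errorCondition("need at least 2 genes",
                        class = c("steadyABC_data_error", "error")))
  }
  R <- cor(t(m), method = "pearson")
  lambda <- 0
  omega <- tryCatch({
    if (rcond(R) < 1e-12) stop("ill-conditioned")
    solve(R)
  }, error = function(e) NULL)
  if (is.null(omega)) {
    lambda <- .shrinkageIntensity(m)
    message(sprintf("correlation matrix singular: shrinking toward identity, lambda = %.4g",
                    lambda))
    Rs <- (1 - lambda) * R
    diag(Rs) <- 1
    omega <- solve(Rs)
  }
  d <- sqrt(diag(omega))
  pcor <- -omega / outer(d, d)
  diag(pcor) <- 1
  attr(pcor, "shrinkage") <- lambda
  pcor
}

# Analytic shrinkage intensity toward the identity for a correlation
# matrix (Schafer-Strimmer): lambda* = sum Var(r_ij) / sum r_ij^2 over
# off-diagonal entries, clipped to [0, 1].
.shrinkageIntensity <- function(m) {
  n <- ncol(m)  # samples
  xs <- t(scale(t(m)))  # standardize genes across samples
  p <- nrow(m)
  num <- 0
  den <- 0
  for (i in seq_len(p - 1)) {
    w <- xs[rep(i, p - i), , drop = FALSE] * xs[(i + 1):p, , drop = FALSE]
    wbar <- rowMeans(w)
    r <- n / (n - 1) * wbar
    vr <- n / (n - 1)^3 * rowSums((w - wbar)^2)
    num <- num + sum(vr)
    den <- den + sum(r^2)
  }
  if (den == 0) return(1)
  min(1, max(0, num / den))
}

#' Threshold correlation and partial correlation into a signed network
#'
#' An edge is attributed between genes i and j iff both `|cor[i,j]|` and
#' `|pcor[i,j]|` reach the threshold (default the stringent 0.99), so the
#' partial-correlation pass prunes indirect links that plain correlation
#' would include. The edge sign is activation for positive correlation and
#' inhibition for negative.
#'
#' @param cor,pcor aligned symmetric matrices with identical dimnames.
#' @param rThreshold absolute correlation threshold in (0, 1].
#' @return An [UndirectedGRN-class] over all genes of the matrices (edges
#'   listed in row-major upper-triangle order).
#' @export
thresholdLinks <- function(cor, pcor, rThreshold = 0.99) {
  if (!identical(dimnames(cor), dimnames(pcor)) ||
      !identical(dim(cor), dim(pcor))) {
    stop(errorCondition("cor and pcor matrices are not aligned",
                        class = c("steadyABC_alignment_error", "error")))
  }
  genes <- rownames(cor)
  from <- character(); to <- character(); sign <- character()
  p <- nrow(cor)
  for (i in seq_len(max(p - 1, 0))) {
    for (j in seq((i + 1), p)) {
      if (abs(cor[i, j]) >= rThreshold && abs(pcor[i, j]) >= rThreshold) {
        from <- c(from, genes[i]); to <- c(to, genes[j])
        sign <- c(sign, if (cor[i, j] > 0) "+" else "-")
      }
    }
  }
  undirectedGRN(nodes = genes,
                edges = data.frame(from = from, to = to, sign = sign,
                                   stringsAsFactors = FALSE))
}

#' Standalone subnetworks of an undirected network
#'
#' Splits the network into its connected components, drops singleton
#' nodes, and orders components by decreasing node count then by the name
#' of their first node; these standalone subnetworks are the units passed
#' on to direction inference.
#'
#' @param grn an [UndirectedGRN-class].
#' @return List of [UndirectedGRN-class] components.
#' @export
networkComponents <- function(grn) {
  stopifnot(is(grn, "UndirectedGRN"))
  if (!edgeCount(grn)) return(list())
  g <- .asIgraph(grn)
  comp <- igraph::components(g)
  membership <- comp$membership[nodeNames(grn)]
  comps <- lapply(seq_len(comp$no), function(k) {
    nodes <- nodeNames(grn)[membership == k]
    if (length(nodes) < 2) return(NULL)
    e <- grn@edges[grn@edges$from %in% nodes, , drop = FALSE]
    rownames(e) <- NULL
    undirectedGRN(nodes = nodes, edges = e)
  })
  comps <- Filter(Negate(is.null), comps)
  sizes <- vapply(comps, function(c) length(nodeNames(c)), integer(1))
  first <- vapply(comps, function(c) nodeNames(c)[1], character(1))
  comps[order(-sizes, first)]
}

#' Log2 fold change between two conditions
#'
#' `log2((mean_b + pseudocount) / (mean_a + pseudocount))` per gene, where
#' means are taken over the samples of each condition. The default
#' pseudocount of 0 makes a zero mean a hard error rather than a silent
#' distortion; pass a positive pseudocount deliberately.
#'
#' @param table an [expressionTable()] with a `condition` column.
#' @param conditionA,conditionB condition names (reference and contrast).
#' @param pseudocount non-negative offset added to both means.
#' @return Named numeric vector of log2 fold changes per gene.
#' @export
log2FoldChange <- function(table, conditionA, conditionB, pseudocount = 0) {
  m <- .abundance(table)
  cond <- SummarizedExperiment::colData(table)$condition
  if (is.null(cond)) {
    stop(errorCondition("table has no condition annotation",
                        class = c("steadyABC_usage_error", "error")))
  }
  for (cc in c(conditionA, conditionB)) {
    if (!any(cond == cc)) {
      stop(errorCondition(sprintf("condition '%s' has no samples", cc),
                          class = c("steadyABC_usage_error", "error")))
    }
  }
  meanA <- rowMeans(m[, cond == conditionA, drop = FALSE])
  meanB <- rowMeans(m[, cond == conditionB, drop = FALSE])
  if (pseudocount == 0 && (any(meanA == 0) || any(meanB == 0))) {
    stop(errorCondition(
      "zero condition mean with pseudocount 0; pass a positive pseudocount",
      class = c("steadyABC_data_error", "error")))
  }
  log2((meanB + pseudocount) / (meanA + pseudocount))
}

#' Filter an expression table by a differential-expression gene list
#'
#' Upstream differential-expression testing happens outside this package;
#' this helper keeps its place in the pipeline by restricting a table to a
#' pre-computed gene list or to genes whose supplied p-values pass a
#' cutoff.
#'
#' @param table an [expressionTable()].
#' @param genes character vector of genes to keep, or `NULL`.
#' @param pValues named numeric vector of per-gene p-values, or `NULL`.
#' @param pCutoff p-value cutoff applied to `pValues`.
#' @return The filtered table.
#' @export
filterDifferential <- function(table, genes = NULL, pValues = NULL,
                               pCutoff = 0.05) {
  keep <- rownames(table)
  if (!is.null(genes)) keep <- intersect(keep, genes)
  if (!is.null(pValues)) {
    keep <- intersect(keep, names(pValues)[pValues <= pCutoff])
  }
  table[keep, ]
}

#' Reconstruct an undirected signed network from an expression table
#'
#' Convenience composition of [pearsonCorrelationMatrix()],
#' [partialCorrelationMatrix()] and [thresholdLinks()].
#'
#' @inheritParams pearsonCorrelationMatrix
#' @inheritParams thresholdLinks
#' @return An [UndirectedGRN-class].
#' @export
inferUndirected <- function(table, rThreshold = 0.99) {
  thresholdLinks(pearsonCorrelationMatrix(table),
                 partialCorrelationMatrix(table),
                 rThreshold = rThreshold)
}
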