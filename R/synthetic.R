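# Run code with a private RNG stream so package functions never disturb
# the caller's .Random.seed.
.withSeed <- function(seed, code) {
  hasSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hasSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hasSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a ground-truth directed network
#'
#' Draws a connected directed acyclic network with exactly `nLinks` links:
#' a random spanning tree over a fixed topological node order guarantees
#' connectivity and acyclicity, then extra forward links are added among
#' the remaining node pairs. Link signs are inhibition with probability
#' `inhibitionFraction`. Fully reproducible from `seed`.
#'
#' @param nNodes number of nodes (named `G1 ... Gn`).
#' @param nLinks number of links, between `nNodes - 1` (a tree) and
#'   `nNodes * (nNodes - 1) / 2`.
#' @param inhibitionFraction probability that a link is inhibitory.
#' @param seed integer RNG seed.
#' @return A [DirectedGRN-class] that is connected and acyclic.
#' @examples
#' generateGroundTruth(4, 3, seed = 1)
#' @export
generateGroundTruth <- function(nNodes, nLinks = nNodes - 1,
                                inhibitionFraction = 0.2, seed = 1) {
  if (nLinks < nNodes - 1 || nLinks > nNodes * (nNodes - 1) / 2) {
    stop(errorCondition(
      sprintf("nLinks must be in [%d, %d] for a connected simple DAG on %d nodes",
              nNodes - 1, nNodes * (nNodes - 1) %/% 2, nNodes),
      class = c("steadyABC_spec_error", "error")))
  }
  nodes <- sprintf("G%d", seq_len(nNodes))
  .withSeed(seed, {
    from <- integer(); to <- integer()
    if (nNodes > 1) {
      # spanning tree: each node (in topological order) picks one parent
      parent <- vapply(2:nNodes, function(i) {
        if (i == 2) 1L else sample.int(i - 1, 1)
      }, integer(1))
      from <- parent
      to <- 2:nNodes
    }
    extra <- nLinks - length(from)
    if (extra > 0) {
      pairs <- which(upper.tri(matrix(0, nNodes, nNodes)), arr.ind = TRUE)
      used <- paste(from, to)
      avail <- pairs[!paste(pairs[, 1], pairs[, 2]) %in% used, , drop = FALSE]
      pick <- avail[sample.int(nrow(avail), extra), , drop = FALSE]
      from <- c(from, pick[, 1])
      to <- c(to, pick[, 2])
    }
    sign <- ifelse(runif(length(from)) < inhibitionFraction, "-", "+")
    directedGRN(nodes = nodes,
                links = data.frame(from = nodes[from], to = nodes[to],
                                   sign = sign, stringsAsFactors = FALSE))
  })
}

#' Simulate observed two-condition expression data from a known network
#'
#' Emulates the experimental design used for direction inference: an
#' unperturbed ("axenic") condition with every node at the baseline
#' independent activity `betaLow`, and a perturbed ("mixed") condition in
#' which `perturbedNodes` are raised to `betaHigh` (standing in for the
#' presence of other species in the culture). Steady states are computed
#' for both conditions; each replicate sample multiplies the steady state
#' by log-normal noise `exp(N(0, noiseSd^2))`. The exact noiseless log2
#' fold-change vector is returned alongside.
#'
#' @param grn a [DirectedGRN-class] ground truth.
#' @param perturbedNodes node subset perturbed in the "mixed" condition;
#'   defaults to the first root (in-degree zero node).
#' @param betaLow,betaHigh baseline and perturbed independent activity.
#' @param noiseSd standard deviation of the multiplicative log-normal
#'   noise on natural-log scale.
#' @param replicates samples per condition.
#' @param seed integer RNG seed for the noise.
#' @param control a [solverControl()] list.
#' @return List with `axenic` and `mixed` [expressionTable()]s, a combined
#'   `table` (both conditions, condition-annotated), and `log2fc`, the
#'   exact steady-state log2 fold changes.
#' @export
simulateObserved <- function(grn, perturbedNodes = NULL,
                             betaLow = 0.01, betaHigh = 0.1,
                             noiseSd = 0, replicates = 3, seed = 1,
                             control = solverControl()) {
  stopifnot(is(grn, "DirectedGRN"))
  nodes <- nodeNames(grn)
  if (is.null(perturbedNodes)) {
    indeg <- table(factor(grn@links$to, levels = nodes))
    perturbedNodes <- nodes[which(indeg == 0)[1]]
  }
  missing <- setdiff(perturbedNodes, nodes)
  if (length(missing)) {
    stop(errorCondition(
      sprintf("perturbed nodes not in network: %s",
              paste(missing, collapse = ", ")),
      class = c("steadyABC_alignment_error", "error")))
  }
  pLow <- modelParameters(grn, beta = betaLow)
  pHigh <- pLow
  pHigh@beta[perturbedNodes] <- betaHigh
  ssAx <- steadyState(grn, pLow, control)
  ssMix <- steadyState(grn, pHigh, control)
  log2fc <- log2(ssMix / ssAx)
  .withSeed(seed, {
    noise <- function(ss, label) {
      m <- vapply(seq_len(replicates), function(r) {
        ss * exp(rnorm(length(ss), 0, noiseSd))
      }, numeric(length(ss)))
      m <- matrix(m, nrow = length(ss),
                  dimnames = list(nodes, sprintf("%s_%d", label,
                                                 seq_len(replicates))))
      m
    }
    axM <- noise(ssAx, "axenic")
    mixM <- noise(ssMix, "mixed")
    list(axenic = expressionTable(axM, rep("axenic", replicates)),
         mixed = expressionTable(mixM, rep("mixed", replicates)),
         table = expressionTable(cbind(axM, mixM),
                                 rep(c("axenic", "mixed"),
                                     each = replicates)),
         log2fc = log2fc)
  })
}

#' Average single-cell style observations into an observed vector
#'
#' Condenses an observations-by-components table (rows are cells or
#' samples, columns are measured components) into one averaged value per
#' component and max-abs scales the result, the form expected by
#' [runABC()] as observed data.
#'
#' @param table numeric matrix or data.frame, observations in rows,
#'   components in columns (named).
#' @return Named numeric vector, one scaled value per component.
#' @export
averageObservations <- function(table) {
  m <- as.matrix(table)
  if (!nrow(m)) {
    stop(errorCondition("need at least one observation row",
                        class = c("steadyABC_data_error", "error")))
  }
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(table, c(1, 2), as.numeric))),
                 arr.ind = TRUE)
    loc <- if (nrow(bad)) {
      sprintf(" (first at row %d, column %d)", bad[1, 1], bad[1, 2])
    } else ""
    stop(errorCondition(paste0("non-numeric cells in observation table", loc),
                        class = c("steadyABC_data_error", "error")))
  }
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)
    stop(errorCondition(
      sprintf("missing value at row %d, column %d", bad[1, 1], bad[1, 2]),
      class = c("steadyABC_data_error", "error")))
  }
  scaleVector(colMeans(m))
}
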