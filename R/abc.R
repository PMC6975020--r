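#' Simulate every (orientation, perturbation) candidate of a network
#'
#' Enumerates all orientations of the undirected network (optionally only
#' the acyclic ones) and, for each orientation and each perturbation
#' condition, computes the scaled sensitivity summary vector and its
#' Euclidean distance to the scaled observed vector. This is the
#' likelihood-free sampling step of the ABC scheme: each candidate is one
#' draw from the uniform prior over link directions, evaluated under one
#' perturbation.
#'
#' @param grn an [UndirectedGRN-class].
#' @param observed named numeric vector over exactly the network nodes
#'   (e.g. log2 fold changes); it is max-abs scaled internally.
#' @param conditions list of [PerturbationCondition-class] objects;
#'   defaults to all single-node perturbations with beta 0.01 to 0.1.
#' @param params function mapping a [DirectedGRN-class] to its
#'   [ModelParameters-class]; defaults to the standard parametrization.
#' @param acyclicOnly drop cyclic orientations before simulating.
#' @param maxLinks enumeration guard, see [enumerateOrientations()].
#' @param control a [solverControl()] list.
#' @return A list of class `steadyABC_candidates` with elements `network`,
#'   `orientations` (bit matrix), `conditions`, `table` (one row per
#'   candidate: `orientation` 0-based index, `condition` index, `distance`,
#'   `converged`), `summaries` (scaled sensitivity matrix, one row per
#'   candidate), `observed` (scaled) and `diagnostics`.
#' @seealso [runABC()] for the full pipeline.
#' @export
simulateCandidates <- function(grn, observed,
                               conditions = perturbationConditions(grn),
                               params = modelParameters,
                               acyclicOnly = FALSE, maxLinks = 24,
                               control = solverControl()) {
  stopifnot(is(grn, "UndirectedGRN"))
  observed <- .alignObserved(observed, grn)
  observedScaled <- scaleVector(observed)
  L <- edgeCount(grn)
  allBits <- enumerateOrientations(grn, acyclicOnly = FALSE,
                                   maxLinks = maxLinks)
  nFilteredCyclic <- 0L
  keepOrient <- rep(TRUE, nrow(allBits))
  dgrns <- vector("list", nrow(allBits))
  for (i in seq_len(nrow(allBits))) {
    dgrns[[i]] <- applyOrientation(grn, allBits[i, ])
    if (acyclicOnly && !isAcyclic(dgrns[[i]])) keepOrient[i] <- FALSE
  }
  nFilteredCyclic <- sum(!keepOrient) * length(conditions)
  orientIdx <- which(keepOrient) - 1L       # 0-based orientation indices
  bits <- allBits[keepOrient, , drop = FALSE]

  nCand <- length(orientIdx) * length(conditions)
  tab <- data.frame(orientation = rep(orientIdx, each = length(conditions)),
                    condition = rep(seq_along(conditions),
                                    times = length(orientIdx)),
                    distance = NA_real_, converged = FALSE)
  summaries <- matrix(NA_real_, nrow = nCand, ncol = length(nodeNames(grn)),
                      dimnames = list(NULL, nodeNames(grn)))
  row <- 0L
  for (i in seq_along(orientIdx)) {
    dgrn <- dgrns[[orientIdx[i] + 1L]]
    p <- params(dgrn)
    for (j in seq_along(conditions)) {
      row <- row + 1L
      eps <- tryCatch(
        sensitivityVector(dgrn, p, conditions[[j]], control),
        steadyABC_convergence_error = function(e) NULL)
      if (is.null(eps)) next
      s <- scaleVector(eps)
      summaries[row, ] <- s
      tab$distance[row] <- euclideanDistance(s, observedScaled)
      tab$converged[row] <- TRUE
    }
  }
  structure(list(network = grn, orientations = bits, conditions = conditions,
                 table = tab, summaries = summaries,
                 observed = observedScaled,
                 diagnostics = list(
                   nTotal = nCand,
                   nNonConverged = sum(!tab$converged),
                   nFilteredCyclic = nFilteredCyclic)),
            class = "steadyABC_candidates")
}

.alignObserved <- function(observed, grn) {
  nodes <- nodeNames(grn)
  if (is.null(names(observed))) {
    stop(errorCondition("observed vector must be named by node",
                        class = c("steadyABC_alignment_error", "error")))
  }
  missing <- setdiff(nodes, names(observed))
  extra <- setdiff(names(observed), nodes)
  if (length(missing) || length(extra)) {
    stop(errorCondition(
      sprintf("observed vector misaligned; missing: [%s], extra: [%s]",
              paste(missing, collapse = ", "),
              paste(extra, collapse = ", ")),
      class = c("steadyABC_alignment_error", "error")))
  }
  observed[nodes]
}

#' Rejection step: keep the best-matching candidates
#'
#' In fraction mode the `ceiling(n * topFraction / 100)` candidates with
#' the smallest distances are kept, extended to include every candidate
#' tied with the distance at the cut, so at least one candidate is always
#' accepted. In threshold mode all candidates with `distance <=
#' distanceThreshold` are kept. Exactly one of the two modes must be given.
#' Non-converged candidates are never ranked.
#'
#' @param candidates a `steadyABC_candidates` object.
#' @param topFraction percentage in (0, 100]; the default 0.1 keeps the
#'   best 0.1 percent of the simulated set.
#' @param distanceThreshold absolute distance cut.
#' @return The candidate table rows accepted, sorted by
#'   (distance, orientation, condition).
#' @export
rejectCandidates <- function(candidates, topFraction = NULL,
                             distanceThreshold = NULL) {
  stopifnot(inherits(candidates, "steadyABC_candidates"))
  if (is.null(topFraction) == is.null(distanceThreshold)) {
    stop(errorCondition(
      "give exactly one of topFraction or distanceThreshold",
      class = c("steadyABC_usage_error", "error")))
  }
  tab <- candidates$table
  ranked <- tab[tab$converged, , drop = FALSE]
  if (!nrow(ranked)) {
    stop(errorCondition("no converged candidates to rank",
                        class = c("steadyABC_usage_error", "error")))
  }
  ord <- order(ranked$distance, ranked$orientation, ranked$condition)
  ranked <- ranked[ord, , drop = FALSE]
  if (!is.null(topFraction)) {
    if (topFraction <= 0 || topFraction > 100) {
      stop(errorCondition("topFraction must be in (0, 100]",
                          class = c("steadyABC_usage_error", "error")))
    }
    k <- ceiling(nrow(ranked) * topFraction / 100)
    cut <- ranked$distance[k]
    accepted <- ranked[ranked$distance <= cut, , drop = FALSE]
  } else {
    accepted <- ranked[ranked$distance <= distanceThreshold, , drop = FALSE]
  }
  rownames(accepted) <- NULL
  accepted
}

#' Posterior probability of each link direction
#'
#' For every edge of the undirected network, the posterior probability that
#' it points in its canonical forward direction is the proportion of
#' accepted candidates whose orientation directs it forward; the posterior
#' of the reverse direction is the complement, so the two always sum to 1.
#'
#' @param accepted accepted candidate rows (from [rejectCandidates()]) or
#'   an [ABCResult-class].
#' @param grn the [UndirectedGRN-class] (ignored for an `ABCResult`).
#' @return data.frame `from`, `to`, `sign`, `posterior`.
#' @export
linkPosteriors <- function(accepted, grn = NULL) {
  if (is(accepted, "ABCResult")) return(accepted@posteriors)
  stopifnot(is(grn, "UndirectedGRN"), is.data.frame(accepted))
  if (!nrow(accepted)) {
    stop(errorCondition("accepted candidate set is empty",
                        class = c("steadyABC_usage_error", "error")))
  }
  L <- edgeCount(grn)
  bits <- orientationBits(accepted$orientation, L)
  post <- if (L) colMeans(bits) else numeric(0)
  out <- grn@edges
  out$posterior <- post
  out
}

#' Percentage of candidates accepted
#'
#' @param nAccepted,nTotal accepted and total candidate counts.
#' @return `100 * nAccepted / nTotal`.
#' @export
acceptanceFraction <- function(nAccepted, nTotal) {
  stopifnot(nTotal > 0, nAccepted >= 0)
  100 * nAccepted / nTotal
}

#' Infer link directions by ABC rejection
#'
#' End-to-end pipeline: enumerate orientations under a uniform prior over
#' link directions, simulate each under every perturbation condition,
#' compare scaled sensitivity summaries to the scaled observed vector by
#' Euclidean distance, reject all but the best-matching candidates, and
#' report per-link posterior direction probabilities. Fully deterministic:
#' the exhaustive path contains no random number generation.
#'
#' @inheritParams simulateCandidates
#' @param maxSubsetSize largest perturbed-subset size for the default
#'   condition set (single-node perturbations by default).
#' @param betaLow,betaHigh perturbed independent activity range.
#' @inheritParams rejectCandidates
#' @return An [ABCResult-class].
#' @examples
#' chain <- undirectedGRN(edges = data.frame(from = c("A", "B"),
#'                                           to = c("B", "C"), sign = "+"))
#' obs <- c(A = 1, B = 0.7, C = 0.5)
#' res <- runABC(chain, obs, topFraction = 25)
#' linkPosteriors(res)
#' @export
runABC <- function(grn, observed, maxSubsetSize = 1,
                   betaLow = 0.01, betaHigh = 0.1,
                   conditions = NULL, params = modelParameters,
                   acyclicOnly = FALSE, maxLinks = 24,
                   topFraction = 0.1, distanceThreshold = NULL,
                   control = solverControl()) {
  stopifnot(is(grn, "UndirectedGRN"))
  if (is.null(conditions)) {
    conditions <- perturbationConditions(grn, maxSubsetSize = maxSubsetSize,
                                         betaLow = betaLow,
                                         betaHigh = betaHigh)
  }
  if (!is.null(distanceThreshold)) topFraction <- NULL
  cand <- simulateCandidates(grn, observed, conditions = conditions,
                             params = params, acyclicOnly = acyclicOnly,
                             maxLinks = maxLinks, control = control)
  accepted <- rejectCandidates(cand, topFraction = topFraction,
                               distanceThreshold = distanceThreshold)
  accepted$perturbed <- vapply(accepted$condition, function(j) {
    paste(cand$conditions[[j]]@perturbed, collapse = ",")
  }, character(1))
  posteriors <- linkPosteriors(accepted, grn)
  diag <- cand$diagnostics
  diag$nAccepted <- nrow(accepted)
  diag$nUniqueAcceptedOrientations <- length(unique(accepted$orientation))
  diag$acceptedOrientationTally <- table(accepted$orientation)
  new("ABCResult",
      network = grn,
      accepted = accepted,
      threshold = max(accepted$distance),
      acceptanceFraction = acceptanceFraction(nrow(accepted),
                                              diag$nTotal),
      totalCandidates = diag$nTotal,
      posteriors = posteriors,
      diagnostics = diag,
      config = list(maxSubsetSize = maxSubsetSize, betaLow = betaLow,
                    betaHigh = betaHigh, nConditions = length(conditions),
                    acyclicOnly = acyclicOnly, maxLinks = maxLinks,
                    topFraction = topFraction,
                    distanceThreshold = distanceThreshold,
                    solver = unclass(control)))
}

#' @rdname acceptedCandidates
#' @export
setGeneric("acceptedCandidates",
           function(x) standardGeneric("acceptedCandidates"))

#' Accessors for ABC results
#'
#' `acceptedCandidates()` returns the accepted candidate table;
#' `abcDiagnostics()` the diagnostics list (candidate totals, non-converged
#' and cyclic-filtered counts, per-orientation acceptance tallies).
#'
#' @param x an [ABCResult-class].
#' @aliases acceptedCandidates abcDiagnostics
#' @export
setMethod("acceptedCandidates", "ABCResult", function(x) x@accepted)

#' @rdname acceptedCandidates
#' @export
setGeneric("abcDiagnostics", function(x) standardGeneric("abcDiagnostics"))

#' @rdname acceptedCandidates
#' @export
setMethod("abcDiagnostics", "ABCResult", function(x) x@diagnostics)

setMethod("show", "ABCResult", function(object) {
  cat(sprintf("ABCResult: %d / %d candidates accepted (%.4g%%), threshold %.6g\n",
              nrow(object@accepted), object@totalCandidates,
              object@acceptanceFraction, object@threshold))
  p <- object@posteriors
  if (nrow(p)) {
    fwd <- p$posterior >= 0.5
    cat("Majority link directions (posterior for the printed direction):\n")
    for (i in seq_len(nrow(p))) {
      arrow <- if (p$sign[i] == "+") "->" else "-|"
      if (fwd[i]) {
        cat(sprintf("  %s %s %s  %.1f%%\n", p$from[i], arrow, p$to[i],
                    100 * p$posterior[i]))
      } else {
        cat(sprintf("  %s %s %s  %.1f%%\n", p$to[i], arrow, p$from[i],
                    100 * (1 - p$posterior[i])))
      }
    }
  }
})
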