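#' @import methods
#' @importFrom stats cor setNames rnorm runif var uniroot
#' @importFrom utils combn head
NULL

edgeKey <- function(from, to) paste0(from, "->", to)

unorderedKey <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

.validSign <- c("+", "-")

.checkEdgeFrame <- function(nodes, edges, directed) {
  what <- if (directed) "links" else "edges"
  if (!is.data.frame(edges) ||
      !all(c("from", "to", "sign") %in% names(edges))) {
    return(sprintf("%s must be a data.frame with columns from, to, sign", what))
  }
  msg <- character()
  if (anyDuplicated(nodes)) msg <- c(msg, "duplicated node names")
  if (any(!nzchar(nodes))) msg <- c(msg, "empty node names")
  bad <- setdiff(c(edges$from, edges$to), nodes)
  if (length(bad)) {
    msg <- c(msg, sprintf("edge endpoints not in node set: %s",
                          paste(unique(bad), collapse = ", ")))
  }
  if (any(edges$from == edges$to)) msg <- c(msg, "self-loops are not allowed")
  if (anyDuplicated(unorderedKey(edges$from, edges$to))) {
    msg <- c(msg, "more than one edge for an unordered node pair")
  }
  if (any(!edges$sign %in% .validSign)) {
    msg <- c(msg, "edge signs must be '+' (activation) or '-' (inhibition)")
  }
  msg
}

#' Undirected signed gene regulatory network
#'
#' A simple undirected graph over named nodes (genes or proteins). Each edge
#' carries a regulatory sign: `"+"` for activation, `"-"` for inhibition.
#' The node order and the `from`/`to` order of every edge are stable and
#' meaningful: they fix the layout of all per-node vectors and define the
#' canonical "forward" direction of each edge used when orientations are
#' enumerated.
#'
#' @slot nodes character vector of unique, non-empty node identifiers.
#' @slot edges data.frame with columns `from`, `to`, `sign`; at most one
#'   edge per unordered node pair, no self-loops.
#' @seealso [undirectedGRN()], [directedGRN()], [enumerateOrientations()]
#' @export
setClass("UndirectedGRN",
  representation(nodes = "character", edges = "data.frame"),
  prototype(nodes = character(),
            edges = data.frame(from = character(), to = character(),
                               sign = character(),
                               stringsAsFactors = FALSE)))

setValidity("UndirectedGRN", function(object) {
  msg <- .checkEdgeFrame(object@nodes, object@edges, directed = FALSE)
  if (length(msg)) msg else TRUE
})

#' Directed signed gene regulatory network
#'
#' One orientation of an [UndirectedGRN-class]: every link points from a
#' regulator (`from`) to its target (`to`) and carries the sign inherited
#' from the undirected edge.
#'
#' @slot nodes character vector of unique node identifiers.
#' @slot links data.frame with columns `from`, `to`, `sign`.
#' @seealso [applyOrientation()], [steadyState()]
#' @export
setClass("DirectedGRN",
  representation(nodes = "character", links = "data.frame"),
  prototype(nodes = character(),
            links = data.frame(from = character(), to = character(),
                               sign = character(),
                               stringsAsFactors = FALSE)))

setValidity("DirectedGRN", function(object) {
  msg <- .checkEdgeFrame(object@nodes, object@links, directed = TRUE)
  if (length(msg)) msg else TRUE
})

#' Parameters of the Hill-type steady-state model
#'
#' Every node has an independent activity `beta` (zero-order production) and
#' a first-order decay rate `delta`; every directed link has a multiplicative
#' scale `alpha`, an activation threshold `gamma` and a Hill exponent `eta`.
#' The standard parametrization sets `delta = alpha = gamma = eta = 1` and
#' `beta = 0.01`; perturbations raise `beta` of selected nodes tenfold.
#'
#' Link-level slots are named by `"from->to"` keys.
#'
#' @slot beta,delta named numeric, one strictly positive value per node.
#' @slot alpha,gamma,eta named numeric, one strictly positive value per link.
#' @seealso [modelParameters()], [steadyState()]
#' @export
setClass("ModelParameters",
  representation(beta = "numeric", delta = "numeric",
                 alpha = "numeric", gamma = "numeric", eta = "numeric"))

setValidity("ModelParameters", function(object) {
  msg <- character()
  for (sl in c("beta", "delta", "alpha", "gamma", "eta")) {
    v <- slot(object, sl)
    if (length(v) && (anyNA(v) || any(!is.finite(v)) || any(v <= 0))) {
      msg <- c(msg, sprintf("all %s values must be finite and > 0", sl))
    }
    if (length(v) && is.null(names(v))) {
      msg <- c(msg, sprintf("%s must be named", sl))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Perturbation of the independent activity of a node subset
#'
#' Describes one in-silico perturbation: the `beta` of every node in
#' `perturbed` is switched from `betaLow` to `betaHigh` (default 0.01 to
#' 0.1, a tenfold increase emulating an external perturbation such as the
#' presence of another species in the culture).
#'
#' @slot perturbed character, non-empty node subset.
#' @slot betaLow,betaHigh positive reals with `betaHigh > betaLow`.
#' @seealso [perturbationConditions()], [sensitivityVector()]
#' @export
setClass("PerturbationCondition",
  representation(perturbed = "character", betaLow = "numeric",
                 betaHigh = "numeric"))

setValidity("PerturbationCondition", function(object) {
  msg <- character()
  if (!length(object@perturbed)) msg <- c(msg, "perturbed set must be non-empty")
  if (length(object@betaLow) != 1 || length(object@betaHigh) != 1 ||
      !is.finite(object@betaLow) || !is.finite(object@betaHigh) ||
      object@betaLow <= 0 || object@betaHigh <= object@betaLow) {
    msg <- c(msg, "need betaHigh > betaLow > 0")
  }
  if (length(msg)) msg else TRUE
})

#' Result of an ABC rejection run over link orientations
#'
#' Holds the accepted candidates (one candidate is an orientation of all
#' links simulated under one perturbation condition), the realized distance
#' threshold and acceptance fraction, the per-link posterior probability
#' that the link points in its canonical forward direction, and diagnostics
#' (non-converged candidates, cyclic orientations filtered, per-orientation
#' acceptance tallies).
#'
#' @slot network the [UndirectedGRN-class] whose links were oriented.
#' @slot accepted data.frame of accepted candidates (orientation index,
#'   bits, condition index, perturbed nodes, distance).
#' @slot threshold realized distance cut.
#' @slot acceptanceFraction percentage of candidates accepted.
#' @slot totalCandidates number of simulated candidates.
#' @slot posteriors data.frame `from`, `to`, `sign`, `posterior` where
#'   `posterior` is the probability the link points `from -> to` as listed
#'   in the undirected network's canonical edge order.
#' @slot diagnostics list of counts and tallies.
#' @slot config list echoing the fully resolved run configuration.
#' @seealso [runABC()], [linkPosteriors()]
#' @export
setClass("ABCResult",
  representation(network = "UndirectedGRN", accepted = "data.frame",
                 threshold = "numeric", acceptanceFraction = "numeric",
                 totalCandidates = "numeric", posteriors = "data.frame",
                 diagnostics = "list", config = "list"))

setValidity("ABCResult", function(object) {
  msg <- character()
  p <- object@posteriors$posterior
  if (length(p) && (anyNA(p) || any(p < 0) || any(p > 1))) {
    msg <- c(msg, "posteriors must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})
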