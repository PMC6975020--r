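#' Enumerate all orientations of an undirected network
#'
#' An orientation assigns a direction to every edge. With `L` edges there
#' are `2^L` orientations; they are generated in the integer order of
#' their bit vectors. Bit `l` of orientation `i` (`i` in `0:(2^L - 1)`) is
#' `bitwAnd(i, 2^(l-1)) > 0`: bit 1 means edge `l` points in its canonical
#' forward direction (`from -> to` as listed in the network), bit 0 means
#' it is reversed.
#'
#' @param grn an [UndirectedGRN-class].
#' @param acyclicOnly keep only orientations whose directed network has no
#'   directed cycle.
#' @param maxLinks guard cap on the edge count (the enumeration is
#'   exponential); raise deliberately for larger runs.
#' @return Integer matrix with one row per orientation and one 0/1 column
#'   per edge, in deterministic order. A network with no edges yields a
#'   single empty orientation (one row, zero columns).
#' @examples
#' path <- undirectedGRN(edges = data.frame(from = c("A", "B"),
#'                                          to = c("B", "C"),
#'                                          sign = "+"))
#' nrow(enumerateOrientations(path))  # 2^2 = 4
#' @export
enumerateOrientations <- function(grn, acyclicOnly = FALSE, maxLinks = 24) {
  stopifnot(is(grn, "UndirectedGRN"))
  L <- edgeCount(grn)
  if (L > maxLinks) {
    stop(errorCondition(
      sprintf(paste0("network has %d links; enumerating 2^%d orientations ",
                     "exceeds the cap of %d links -- raise maxLinks to force"),
              L, L, maxLinks),
      class = c("steadyABC_size_error", "error")))
  }
  bits <- orientationBits(seq_len(2^L) - 1, L)
  if (acyclicOnly && L > 0) {
    keep <- vapply(seq_len(nrow(bits)), function(i) {
      isAcyclic(applyOrientation(grn, bits[i, ]))
    }, logical(1))
    bits <- bits[keep, , drop = FALSE]
  }
  bits
}

#' Bit vectors of orientation indices
#'
#' @param index integer vector of orientation indices in `0:(2^L - 1)`.
#' @param L number of edges.
#' @return Integer 0/1 matrix with `length(index)` rows and `L` columns.
#' @export
orientationBits <- function(index, L) {
  stopifnot(all(index >= 0), all(index < 2^L))
  m <- matrix(0L, nrow = length(index), ncol = L)
  for (l in seq_len(L)) {
    m[, l] <- as.integer(index %/% 2^(l - 1) %% 2)
  }
  m
}

#' Direct an undirected network according to an orientation
#'
#' @param grn an [UndirectedGRN-class].
#' @param bits 0/1 vector of length `edgeCount(grn)`; 1 keeps edge `l` in
#'   its canonical `from -> to` direction, 0 reverses it. Signs carry over
#'   unchanged.
#' @return A [DirectedGRN-class] over the same nodes.
#' @export
applyOrientation <- function(grn, bits) {
  stopifnot(is(grn, "UndirectedGRN"))
  bits <- as.integer(bits)
  if (length(bits) != edgeCount(grn) || any(!bits %in% c(0L, 1L))) {
    stop(errorCondition(
      sprintf("orientation has %d bits but the network has %d edges",
              length(bits), edgeCount(grn)),
      class = c("steadyABC_structure_error", "error")))
  }
  e <- grn@edges
  links <- data.frame(
    from = ifelse(bits == 1L, e$from, e$to),
    to   = ifelse(bits == 1L, e$to, e$from),
    sign = e$sign, stringsAsFactors = FALSE)
  new("DirectedGRN", nodes = grn@nodes, links = links)
}

#' Recover the orientation bits of a directed network
#'
#' Inverse of [applyOrientation()]: matches each directed link against the
#' canonical edge list of the undirected reference.
#'
#' @param dgrn a [DirectedGRN-class].
#' @param grn the [UndirectedGRN-class] it orients.
#' @return 0/1 integer vector of length `edgeCount(grn)`.
#' @export
orientationOf <- function(dgrn, grn) {
  stopifnot(is(dgrn, "DirectedGRN"), is(grn, "UndirectedGRN"))
  e <- grn@edges
  l <- dgrn@links
  if (nrow(e) != nrow(l)) {
    stop(errorCondition("link counts differ",
                        class = c("steadyABC_structure_error", "error")))
  }
  key <- setNames(seq_len(nrow(l)), unorderedKey(l$from, l$to))
  idx <- key[unorderedKey(e$from, e$to)]
  if (anyNA(idx)) {
    stop(errorCondition("directed links do not match the undirected edges",
                        class = c("steadyABC_structure_error", "error")))
  }
  as.integer(l$from[idx] == e$from & l$to[idx] == e$to)
}

#' Test a directed network for acyclicity
#'
#' @param grn a [DirectedGRN-class].
#' @return `TRUE` iff the network has no directed cycle.
#' @export
isAcyclic <- function(grn) {
  stopifnot(is(grn, "DirectedGRN"))
  if (!edgeCount(grn)) return(TRUE)
  igraph::is_dag(.asIgraph(grn))
}

#' Construct a single perturbation condition
#'
#' @param perturbed character vector of perturbed node names.
#' @param betaLow,betaHigh independent activity before and after the
#'   perturbation (default a tenfold increase, 0.01 to 0.1).
#' @return A [PerturbationCondition-class].
#' @export
perturbationCondition <- function(perturbed, betaLow = 0.01, betaHigh = 0.1) {
  new("PerturbationCondition", perturbed = as.character(perturbed),
      betaLow = betaLow, betaHigh = betaHigh)
}

#' Enumerate perturbation conditions over node subsets
#'
#' Yields every non-empty node subset of size at most `maxSubsetSize`,
#' ordered by subset size and then lexicographically in the node order, so
#' the sequence is identical across runs. Each condition raises the
#' independent activity of its subset from `betaLow` to `betaHigh`.
#'
#' @param nodes ordered character vector of node names (or a network).
#' @param maxSubsetSize largest subset size, between 1 and `length(nodes)`.
#' @inheritParams perturbationCondition
#' @return List of [PerturbationCondition-class] objects.
#' @examples
#' length(perturbationConditions(c("A", "B", "C"), maxSubsetSize = 2))  # 6
#' @export
perturbationConditions <- function(nodes, maxSubsetSize = 1,
                                   betaLow = 0.01, betaHigh = 0.1) {
  if (is(nodes, "UndirectedGRN") || is(nodes, "DirectedGRN")) {
    nodes <- nodeNames(nodes)
  }
  n <- length(nodes)
  if (maxSubsetSize < 1 || maxSubsetSize > n) {
    stop(errorCondition(
      sprintf("maxSubsetSize must be in [1, %d]", n),
      class = c("steadyABC_parameter_error", "error")))
  }
  out <- list()
  for (size in seq_len(maxSubsetSize)) {
    sets <- combn(seq_len(n), size, simplify = FALSE)
    out <- c(out, lapply(sets, function(ix) {
      perturbationCondition(nodes[ix], betaLow, betaHigh)
    }))
  }
  out
}

#' Monte Carlo orientation sampling (not implemented)
#'
#' Random sampling of the orientation space is a documented alternative to
#' exhaustive enumeration for large networks; this interface is reserved
#' and deliberately not implemented.
#'
#' @param grn an [UndirectedGRN-class].
#' @param n number of orientations to draw.
#' @export
sampleOrientations <- function(grn, n) {
  stop(errorCondition(
    "Monte Carlo orientation sampling is not implemented; use enumerateOrientations()",
    class = c("steadyABC_not_implemented", "error")))
}
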