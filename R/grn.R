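#' Construct an undirected signed network
#'
#' @param nodes character vector of node names; defaults to the names
#'   appearing in `edges` in order of first appearance.
#' @param edges data.frame (or matrix coercible to one) with columns
#'   `from`, `to`, `sign` (`"+"` activation, `"-"` inhibition). The row
#'   order defines the canonical forward direction of each edge.
#' @return An [UndirectedGRN-class].
#' @examples
#' g <- undirectedGRN(edges = data.frame(from = c("A", "B"),
#'                                       to   = c("B", "C"),
#'                                       sign = c("+", "-")))
#' edgeCount(g)
#' @export
undirectedGRN <- function(nodes = NULL, edges = NULL) {
  edges <- .asEdgeFrame(edges)
  if (is.null(nodes)) {
    nodes <- unique(c(rbind(edges$from, edges$to)))
  }
  new("UndirectedGRN", nodes = as.character(nodes), edges = edges)
}

#' Construct a directed signed network
#'
#' @inheritParams undirectedGRN
#' @param links data.frame with columns `from`, `to`, `sign`; each link
#'   points from regulator to target.
#' @return A [DirectedGRN-class].
#' @examples
#' chain <- directedGRN(links = data.frame(from = "X", to = "Y", sign = "+"))
#' isAcyclic(chain)
#' @export
directedGRN <- function(nodes = NULL, links = NULL) {
  links <- .asEdgeFrame(links)
  if (is.null(nodes)) {
    nodes <- unique(c(rbind(links$from, links$to)))
  }
  new("DirectedGRN", nodes = as.character(nodes), links = links)
}

.asEdgeFrame <- function(edges) {
  if (is.null(edges)) {
    edges <- data.frame(from = character(), to = character(),
                        sign = character(), stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) && !all(c("from", "to", "sign") %in% names(edges))) {
    stop("edges need columns 'from', 'to' and 'sign'", call. = FALSE)
  }
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$sign <- as.character(edges$sign)
  rownames(edges) <- NULL
  edges
}

#' @rdname nodeNames
#' @export
setGeneric("nodeNames", function(x) standardGeneric("nodeNames"))

#' Node and edge accessors
#'
#' `nodeNames()` returns the ordered node identifiers; `edgeTable()` the
#' edge (or link) data.frame with columns `from`, `to`, `sign`;
#' `edgeCount()` the number of edges.
#'
#' @param x an [UndirectedGRN-class] or [DirectedGRN-class].
#' @return `nodeNames()`: character; `edgeTable()`: data.frame;
#'   `edgeCount()`: integer.
#' @aliases nodeNames edgeTable edgeCount
#' @export
setMethod("nodeNames", "UndirectedGRN", function(x) x@nodes)

#' @rdname nodeNames
#' @export
setMethod("nodeNames", "DirectedGRN", function(x) x@nodes)

#' @rdname nodeNames
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname nodeNames
#' @export
setMethod("edgeTable", "UndirectedGRN", function(x) x@edges)

#' @rdname nodeNames
#' @export
setMethod("edgeTable", "DirectedGRN", function(x) x@links)

#' @rdname nodeNames
#' @export
setGeneric("edgeCount", function(x) standardGeneric("edgeCount"))

#' @rdname nodeNames
#' @export
setMethod("edgeCount", "UndirectedGRN", function(x) nrow(x@edges))

#' @rdname nodeNames
#' @export
setMethod("edgeCount", "DirectedGRN", function(x) nrow(x@links))

setMethod("show", "UndirectedGRN", function(object) {
  cat(sprintf("UndirectedGRN: %d nodes, %d edges\n",
              length(object@nodes), nrow(object@edges)))
  if (nrow(object@edges)) {
    arrows <- ifelse(object@edges$sign == "+", "--", "--|")
    cat(paste0("  ", object@edges$from, " ", arrows, " ",
               object@edges$to, collapse = "\n"), "\n")
  }
})

setMethod("show", "DirectedGRN", function(object) {
  cat(sprintf("DirectedGRN: %d nodes, %d links\n",
              length(object@nodes), nrow(object@links)))
  if (nrow(object@links)) {
    arrows <- ifelse(object@links$sign == "+", "->", "-|")
    cat(paste0("  ", object@links$from, " ", arrows, " ",
               object@links$to, collapse = "\n"), "\n")
  }
})

setMethod("show", "PerturbationCondition", function(object) {
  cat(sprintf("PerturbationCondition: beta %g -> %g on {%s}\n",
              object@betaLow, object@betaHigh,
              paste(object@perturbed, collapse = ", ")))
})

.asIgraph <- function(grn) {
  directed <- is(grn, "DirectedGRN")
  igraph::graph_from_data_frame(edgeTable(grn)[, c("from", "to")],
                                directed = directed,
                                vertices = nodeNames(grn))
}
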