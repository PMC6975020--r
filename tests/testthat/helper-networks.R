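# Small network builders used across tests.

chainUGRN <- function(nodes = c("A", "B", "C"), signs = "+") {
  n <- length(nodes)
  undirectedGRN(nodes = nodes,
                edges = data.frame(from = nodes[-n], to = nodes[-1],
                                   sign = rep_len(signs, n - 1),
                                   stringsAsFactors = FALSE))
}

chainDGRN <- function(nodes = c("A", "B", "C"), signs = "+") {
  n <- length(nodes)
  directedGRN(nodes = nodes,
              links = data.frame(from = nodes[-n], to = nodes[-1],
                                 sign = rep_len(signs, n - 1),
                                 stringsAsFactors = FALSE))
}

triangleUGRN <- function() {
  undirectedGRN(nodes = c("A", "B", "C"),
                edges = data.frame(from = c("A", "B", "C"),
                                   to = c("B", "C", "A"),
                                   sign = "+", stringsAsFactors = FALSE))
}
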