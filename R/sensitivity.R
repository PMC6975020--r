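#' Sensitivity summary statistics of a directed network
#'
#' Simulates the network to steady state at the low and high independent
#' activity of the perturbed nodes and returns, per node \eqn{N}, the
#' logarithmic sensitivity
#' \deqn{\varepsilon_N = \frac{\ln(SS_{high}(N) / SS_{low}(N))}
#'   {\ln(\beta_{high} / \beta_{low})}}
#' i.e. the relative steady-state response of each node to the perturbed
#' parameter change. A node proportional to its own beta has sensitivity 1
#' to its own perturbation; nodes unreachable from the perturbed set have
#' sensitivity 0. When several nodes are perturbed they switch together and
#' the denominator is the single shared log ratio.
#'
#' @param grn a [DirectedGRN-class].
#' @param params baseline [ModelParameters-class]; the perturbed nodes'
#'   `beta` is overridden by the condition in both states.
#' @param condition a [PerturbationCondition-class].
#' @param control a [solverControl()] list.
#' @return Named numeric vector of sensitivities, one per node.
#' @examples
#' g <- directedGRN(nodes = "X")
#' sensitivityVector(g, condition = perturbationCondition("X"))  # 1
#' @export
sensitivityVector <- function(grn, params = modelParameters(grn),
                              condition, control = solverControl()) {
  stopifnot(is(grn, "DirectedGRN"), is(condition, "PerturbationCondition"))
  validObject(condition)
  missing <- setdiff(condition@perturbed, nodeNames(grn))
  if (length(missing)) {
    stop(errorCondition(
      sprintf("perturbed nodes not in network: %s",
              paste(missing, collapse = ", ")),
      class = c("steadyABC_alignment_error", "error")))
  }
  low <- params
  low@beta[condition@perturbed] <- condition@betaLow
  high <- params
  high@beta[condition@perturbed] <- condition@betaHigh
  ssLow <- steadyState(grn, low, control)
  ssHigh <- steadyState(grn, high, control)
  if (any(ssLow <= 0) || any(ssHigh <= 0)) {
    stop(errorCondition(
      "zero steady-state activity: the log sensitivity ratio is undefined",
      class = c("steadyABC_numerical_error", "error")))
  }
  log(ssHigh / ssLow) / log(condition@betaHigh / condition@betaLow)
}

#' Scale a vector to maximum absolute value one
#'
#' Divides every component by `max(abs(v))`, preserving signs and ratios,
#' so simulated and observed summary vectors become scale-free before
#' comparison. All-zero vectors are returned unchanged. Idempotent.
#'
#' @param v finite numeric vector.
#' @return Numeric vector with `max(abs(.)) <= 1`.
#' @examples
#' scaleVector(c(2, -4, 1))
#' @export
scaleVector <- function(v) {
  if (anyNA(v) || any(!is.finite(v))) {
    stop(errorCondition("cannot scale a vector with non-finite values",
                        class = c("steadyABC_data_error", "error")))
  }
  m <- max(abs(v), 0)
  if (m == 0) v else v / m
}

#' Euclidean distance between aligned summary vectors
#'
#' Both vectors must cover the same node set; named vectors are aligned by
#' name, and any mismatch is an error listing the offending identifiers.
#'
#' @param a,b numeric vectors (named by node, or unnamed and equal length).
#' @return Non-negative scalar, the l2 norm of `a - b`.
#' @export
euclideanDistance <- function(a, b) {
  if (!is.null(names(a)) || !is.null(names(b))) {
    extra <- setdiff(names(b), names(a))
    missing <- setdiff(names(a), names(b))
    if (length(extra) || length(missing)) {
      stop(errorCondition(
        sprintf("node sets differ; missing: [%s], extra: [%s]",
                paste(missing, collapse = ", "),
                paste(extra, collapse = ", ")),
        class = c("steadyABC_alignment_error", "error")))
    }
    b <- b[names(a)]
  } else if (length(a) != length(b)) {
    stop(errorCondition("vectors have different lengths",
                        class = c("steadyABC_alignment_error", "error")))
  }
  sqrt(sum((a - b)^2))
}
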