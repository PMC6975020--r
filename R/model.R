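#' Build a parameter set for a directed network
#'
#' Returns the standard parametrization unless overridden: every node gets
#' independent activity `beta = 0.01` and decay `delta = 1`; every link gets
#' scale `alpha = 1`, threshold `gamma = 1` and Hill exponent `eta = 1`.
#' Overrides are named vectors: node-level by node name, link-level by
#' `"from->to"` key; unnamed scalars apply to all nodes/links.
#'
#' @param grn a [DirectedGRN-class].
#' @param beta,delta per-node parameters (scalar or named vector).
#' @param alpha,gamma,eta per-link parameters (scalar or named vector).
#' @return A [ModelParameters-class].
#' @examples
#' g <- directedGRN(links = data.frame(from = "X", to = "Y", sign = "+"))
#' p <- modelParameters(g)
#' p@beta
#' @export
modelParameters <- function(grn, beta = 0.01, delta = 1,
                            alpha = 1, gamma = 1, eta = 1) {
  stopifnot(is(grn, "DirectedGRN"))
  nodes <- nodeNames(grn)
  keys <- edgeKey(grn@links$from, grn@links$to)
  new("ModelParameters",
      beta  = .expandParam(beta, nodes, "beta"),
      delta = .expandParam(delta, nodes, "delta"),
      alpha = .expandParam(alpha, keys, "alpha"),
      gamma = .expandParam(gamma, keys, "gamma"),
      eta   = .expandParam(eta, keys, "eta"))
}

.expandParam <- function(value, keys, what) {
  if (is.null(names(value))) {
    if (length(value) != 1 && length(value) != length(keys)) {
      stop(sprintf("unnamed %s must be a scalar or one value per entry", what),
           call. = FALSE)
    }
    return(setNames(rep_len(as.numeric(value), length(keys)), keys))
  }
  out <- setNames(rep_len(NA_real_, length(keys)), keys)
  unknown <- setdiff(names(value), keys)
  if (length(unknown)) {
    stop(sprintf("%s override names not in network: %s", what,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  out[names(value)] <- as.numeric(value)
  if (anyNA(out)) {
    # partial named overrides fall back to 1 only via explicit default
    stop(sprintf("named %s overrides must cover every entry or use the scalar form",
                 what), call. = FALSE)
  }
  out
}

.checkParamsCover <- function(grn, params) {
  nodes <- nodeNames(grn)
  keys <- edgeKey(grn@links$from, grn@links$to)
  missNode <- c(setdiff(nodes, names(params@beta)),
                setdiff(nodes, names(params@delta)))
  missLink <- c(setdiff(keys, names(params@alpha)),
                setdiff(keys, names(params@gamma)),
                setdiff(keys, names(params@eta)))
  if (length(missNode) || length(missLink)) {
    stop(errorCondition(
      sprintf("parameters missing for: %s",
              paste(unique(c(missNode, missLink)), collapse = ", ")),
      class = c("steadyABC_configuration_error", "error")))
  }
}

#' Assemble the ODE right-hand side of a directed network
#'
#' The activity of a node \eqn{Y} with incoming activators \eqn{A_i} and
#' inhibitors \eqn{I_j} evolves as
#' \deqn{dY/dt = -\delta_Y Y + (\beta_Y + \sum_i Act_i(X_{A_i}))
#'   \prod_j Inh_j(X_{I_j})}
#' i.e. activation terms add to the independent activity while inhibition
#' terms multiply the resulting production. A node without inputs reduces
#' to the linear source-decay system \eqn{dY/dt = -\delta_Y Y + \beta_Y}.
#'
#' @param grn a [DirectedGRN-class].
#' @param params a [ModelParameters-class] covering every node and link.
#' @return A function mapping a named activity vector to the named vector
#'   of time derivatives.
#' @examples
#' g <- directedGRN(links = data.frame(from = "X", to = "Y", sign = "+"))
#' rhs <- assembleRHS(g, modelParameters(g))
#' rhs(c(X = 0.01, Y = 0))
#' @export
assembleRHS <- function(grn, params) {
  stopifnot(is(grn, "DirectedGRN"), is(params, "ModelParameters"))
  .checkParamsCover(grn, params)
  nodes <- nodeNames(grn)
  links <- grn@links
  keys <- edgeKey(links$from, links$to)
  beta <- params@beta[nodes]
  delta <- params@delta[nodes]
  alpha <- params@alpha[keys]
  gamma <- params@gamma[keys]
  eta <- params@eta[keys]
  src <- match(links$from, nodes)
  tgt <- match(links$to, nodes)
  act <- links$sign == "+"
  function(state) {
    x <- state[nodes]
    production <- beta
    inhibition <- rep(1, length(nodes))
    if (length(src)) {
      xs <- x[src]
      xe <- xs^eta
      ge <- gamma^eta
      hA <- alpha * xe / (xe + ge)
      hI <- alpha * ge / (xe + ge)
      for (l in seq_along(src)) {
        if (act[l]) production[tgt[l]] <- production[tgt[l]] + hA[l]
        else inhibition[tgt[l]] <- inhibition[tgt[l]] * hI[l]
      }
    }
    setNames(-delta * x + production * inhibition, nodes)
  }
}

#' Solver settings for the steady-state integration
#'
#' The steady state is found by integrating the network ODEs with a
#' fixed-step explicit fourth-order Runge-Kutta scheme from the
#' interaction-free fixed point (every node at `beta/delta`) until the
#' largest absolute derivative falls below `tol`, or failing with a
#' convergence error at `tMax` time units.
#'
#' @param step RK4 step size in model time units.
#' @param tol convergence tolerance on `max |dX/dt|`.
#' @param tMax maximum integrated time before a convergence error.
#' @return A list of class `steadyABC_solver_control`.
#' @export
solverControl <- function(step = 0.01, tol = 1e-9, tMax = 1e4) {
  stopifnot(step > 0, tol > 0, tMax > 0)
  structure(list(step = step, tol = tol, tMax = tMax),
            class = "steadyABC_solver_control")
}

#' Steady state of a directed network
#'
#' Integrates the Hill-type ODE system (see [assembleRHS()]) to its steady
#' state. Deterministic given the network, parameters and control settings;
#' activities are clipped at zero if integration undershoots by numerical
#' round-off. Non-convergence raises a condition of class
#' `steadyABC_convergence_error` carrying the last state and residual.
#'
#' @inheritParams assembleRHS
#' @param control a [solverControl()] list.
#' @return Named numeric vector of non-negative steady-state activities.
#' @examples
#' g <- directedGRN(nodes = "X")
#' steadyState(g, modelParameters(g))  # beta / delta = 0.01
#' @export
steadyState <- function(grn, params = modelParameters(grn),
                        control = solverControl()) {
  stopifnot(is(grn, "DirectedGRN"), is(params, "ModelParameters"))
  .checkParamsCover(grn, params)
  nodes <- nodeNames(grn)
  links <- grn@links
  keys <- edgeKey(links$from, links$to)
  res <- rk4_steady_state(
    x0 = as.numeric(params@beta[nodes] / params@delta[nodes]),
    src = match(links$from, nodes) - 1L,
    tgt = match(links$to, nodes) - 1L,
    activation = links$sign == "+",
    alpha = as.numeric(params@alpha[keys]),
    gamma = as.numeric(params@gamma[keys]),
    eta = as.numeric(params@eta[keys]),
    beta = as.numeric(params@beta[nodes]),
    delta = as.numeric(params@delta[nodes]),
    step = control$step, tol = control$tol, tMax = control$tMax)
  state <- setNames(res$state, nodes)
  if (!res$converged) {
    stop(errorCondition(
      sprintf("steady state not reached by t = %g (residual %.3g)",
              control$tMax, res$residual),
      class = c("steadyABC_convergence_error", "error"),
      state = state, residual = res$residual))
  }
  state
}
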