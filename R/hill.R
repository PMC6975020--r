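.checkHillParams <- function(alpha, gamma, eta) {
  if (any(!is.finite(alpha)) || any(alpha <= 0) ||
      any(!is.finite(gamma)) || any(gamma <= 0) ||
      any(!is.finite(eta)) || any(eta <= 0)) {
    stop(errorCondition("alpha, gamma and eta must be finite and > 0",
                        class = c("steadyABC_parameter_error", "error")))
  }
}

#' Hill-type transfer functions for regulatory links
#'
#' `hillActivation()` is the saturating response
#' \eqn{\alpha x^\eta / (x^\eta + \gamma^\eta)} of a target to an
#' activating regulator at activity `x`; `hillInhibition()` is the
#' complementary decreasing response
#' \eqn{\alpha \gamma^\eta / (x^\eta + \gamma^\eta)}. `gamma` is the
#' half-response threshold (the activation reaches \eqn{\alpha/2} at
#' `x = gamma`), `eta` the Hill exponent controlling steepness, and
#' `alpha` a multiplicative scale. For equal parameters the two functions
#' sum to `alpha`.
#'
#' @param x non-negative regulator activity (vectorized).
#' @param alpha,gamma,eta strictly positive link parameters.
#' @return Numeric of the same length as `x`, in `[0, alpha]`.
#' @examples
#' hillActivation(1, 1, 1, 1)   # half-maximum: 0.5
#' hillInhibition(0, 1, 1, 1)   # no inhibitor present: 1
#' @export
hillActivation <- function(x, alpha = 1, gamma = 1, eta = 1) {
  .checkHillParams(alpha, gamma, eta)
  if (any(!is.finite(x)) || any(x < 0)) {
    stop(errorCondition("regulator activity x must be finite and >= 0",
                        class = c("steadyABC_parameter_error", "error")))
  }
  xe <- x^eta
  alpha * xe / (xe + gamma^eta)
}

#' @rdname hillActivation
#' @export
hillInhibition <- function(x, alpha = 1, gamma = 1, eta = 1) {
  .checkHillParams(alpha, gamma, eta)
  if (any(!is.finite(x)) || any(x < 0)) {
    stop(errorCondition("regulator activity x must be finite and >= 0",
                        class = c("steadyABC_parameter_error", "error")))
  }
  ge <- gamma^eta
  alpha * ge / (x^eta + ge)
}
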