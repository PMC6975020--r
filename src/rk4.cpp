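#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Right-hand side of the Hill-type GRN ODE system.
// dx[k] = -delta[k] * x[k] + (beta[k] + sum_i Act_i) * prod_j Inh_j
static void grn_rhs(const std::vector<double>& x,
                    std::vector<double>& dx,
                    const IntegerVector& src, const IntegerVector& tgt,
                    const LogicalVector& activation,
                    const NumericVector& alpha, const NumericVector& gamma,
                    const NumericVector& eta,
                    const NumericVector& beta, const NumericVector& delta,
                    std::vector<double>& act, std::vector<double>& inh) {
  const int n = x.size();
  const int m = src.size();
  for (int k = 0; k < n; ++k) { act[k] = 0.0; inh[k] = 1.0; }
  for (int l = 0; l < m; ++l) {
    double xs = x[src[l]];
    if (xs < 0.0) xs = 0.0;  // guard transient round-off undershoot
    const double xe = std::pow(xs, eta[l]);
    const double ge = std::pow(gamma[l], eta[l]);
    if (activation[l]) act[tgt[l]] += alpha[l] * xe / (xe + ge);
    else               inh[tgt[l]] *= alpha[l] * ge / (xe + ge);
  }
  for (int k = 0; k < n; ++k)
    dx[k] = -delta[k] * x[k] + (beta[k] + act[k]) * inh[k];
}

// Fixed-step explicit RK4 integration until max |dx/dt| < tol or t >= tMax.
// [[Rcpp::export]]
List rk4_steady_state(NumericVector x0,
                      IntegerVector src, IntegerVector tgt,
                      LogicalVector activation,
                      NumericVector alpha, NumericVector gamma,
                      NumericVector eta,
                      NumericVector beta, NumericVector delta,
                      double step, double tol, double tMax) {
  const int n = x0.size();
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> k1(n), k2(n), k3(n), k4(n), xt(n), act(n), inh(n);

  double t = 0.0, residual = R_PosInf;
  bool converged = false;
  const long maxSteps = (long)std::ceil(tMax / step);

  grn_rhs(x, k1, src, tgt, activation, alpha, gamma, eta, beta, delta, act, inh);
  residual = 0.0;
  for (int k = 0; k < n; ++k) residual = std::max(residual, std::fabs(k1[k]));
  if (residual < tol) converged = true;

  for (long s = 0; s < maxSteps && !converged; ++s) {
    // k1 already holds f(x)
    for (int k = 0; k < n; ++k) xt[k] = x[k] + 0.5 * step * k1[k];
    grn_rhs(xt, k2, src, tgt, activation, alpha, gamma, eta, beta, delta, act, inh);
    for (int k = 0; k < n; ++k) xt[k] = x[k] + 0.5 * step * k2[k];
    grn_rhs(xt, k3, src, tgt, activation, alpha, gamma, eta, beta, delta, act, inh);
    for (int k = 0; k < n; ++k) xt[k] = x[k] + step * k3[k];
    grn_rhs(xt, k4, src, tgt, activation, alpha, gamma, eta, beta, delta, act, inh);
    for (int k = 0; k < n; ++k) {
      x[k] += step / 6.0 * (k1[k] + 2.0 * k2[k] + 2.0 * k3[k] + k4[k]);
      if (x[k] < 0.0) x[k] = 0.0;  // biological activities are non-negative
    }
    t += step;
    grn_rhs(x, k1, src, tgt, activation, alpha, gamma, eta, beta, delta, act, inh);
    residual = 0.0;
    for (int k = 0; k < n; ++k) residual = std::max(residual, std::fabs(k1[k]));
    if (residual < tol) converged = true;
  }

  return List::create(_["state"] = NumericVector(x.begin(), x.end()),
                      _["residual"] = residual,
                      _["converged"] = converged,
                      _["t"] = t);
}
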