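#include <Rcpp.h>
using namespace Rcpp;

// Gauss-Seidel solve of the global balance equations pi Q = 0 on a CTMC
// generator in column-compressed form (the layout of a dgCMatrix).  For
// each state j the balance reads sum_{i != j} pi_i q_ij = pi_j * out_j
// with out_j = -q_jj; sweeping the states with in-place updates converges
// for irreducible generators (the classic iterative scheme of
// probabilistic model checkers).  Slow-mixing chains (e.g. relays without
// hydrolysis at the output layer) leave one dominant error mode that
// decays geometrically; when successive sweep differences shrink by a
// stable ratio r, Aitken extrapolation pi += d * r / (1 - r) removes that
// mode in one step.  The iterate is renormalized each sweep and
// convergence is declared on the infinity-norm balance residual relative
// to the largest exit rate.
//
// colptr, rowind, xval: column-compressed Q (with diagonal entries).
// Returns the stationary distribution; attribute "sweeps" reports the
// sweep count, "residual" the final relative residual.

// [[Rcpp::export]]
NumericVector stationary_gs(IntegerVector colptr, IntegerVector rowind,
                            NumericVector xval, int n,
                            int max_sweeps = 200000, double tol = 1e-12,
                            Nullable<NumericVector> init = R_NilValue) {
  NumericVector pi(n, 1.0 / n);
  if (init.isNotNull()) {
    NumericVector w(init);
    if (w.size() == n) {
      double s = 0.0;
      for (int j = 0; j < n; ++j) s += std::max(w[j], 0.0);
      if (s > 0.0) for (int j = 0; j < n; ++j) pi[j] = std::max(w[j], 0.0) / s;
    }
  }
  std::vector<double> out(n, 0.0);
  for (int j = 0; j < n; ++j) {
    for (int k = colptr[j]; k < colptr[j + 1]; ++k) {
      if (rowind[k] == j) out[j] = -xval[k];
    }
  }
  double maxout = 0.0;
  for (int j = 0; j < n; ++j) maxout = std::max(maxout, out[j]);
  if (n == 1) {
    pi[0] = 1.0;
    pi.attr("sweeps") = 0;
    pi.attr("residual") = 0.0;
    return pi;
  }
  if (maxout <= 0.0) stop("generator has no transitions");
  for (int j = 0; j < n; ++j)
    if (out[j] <= 0.0)
      stop("absorbing state inside the communicating class");

  std::vector<double> prev(n), diff(n);
  double dnorm_prev = -1.0;
  double resid = R_PosInf;
  int sweep = 0, stable = 0;
  for (; sweep < max_sweeps; ++sweep) {
    for (int j = 0; j < n; ++j) prev[j] = pi[j];
    for (int j = 0; j < n; ++j) {
      double acc = 0.0;
      for (int k = colptr[j]; k < colptr[j + 1]; ++k) {
        int i = rowind[k];
        if (i != j) acc += pi[i] * xval[k];
      }
      pi[j] = acc / out[j];
    }
    double s = 0.0;
    for (int j = 0; j < n; ++j) s += pi[j];
    if (s <= 0.0) stop("iterate collapsed to zero");
    double dnorm = 0.0;
    for (int j = 0; j < n; ++j) {
      pi[j] /= s;
      diff[j] = pi[j] - prev[j];
      dnorm += std::fabs(diff[j]);
    }
    // geometric decay of one dominant mode -> extrapolate it away
    if (dnorm_prev > 0.0 && dnorm > 0.0) {
      double r = dnorm / dnorm_prev;
      if (r > 0.5 && r < 0.9999) ++stable; else stable = 0;
      if (stable >= 5) {
        double f = r / (1.0 - r);
        double s2 = 0.0;
        for (int j = 0; j < n; ++j) {
          pi[j] = std::max(pi[j] + f * diff[j], 0.0);
          s2 += pi[j];
        }
        for (int j = 0; j < n; ++j) pi[j] /= s2;
        stable = 0;
        dnorm = -1.0;  // restart ratio tracking
      }
    }
    dnorm_prev = dnorm;
    if (sweep % 10 == 9 || sweep == max_sweeps - 1) {
      double res = 0.0;
      for (int j = 0; j < n; ++j) {
        double acc = 0.0;
        for (int k = colptr[j]; k < colptr[j + 1]; ++k)
          acc += pi[rowind[k]] * xval[k];
        res = std::max(res, std::fabs(acc));
      }
      resid = res / maxout;
      if (resid < tol) { ++sweep; break; }
    }
  }
  pi.attr("sweeps") = sweep;
  pi.attr("residual") = resid;
  return pi;
}
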