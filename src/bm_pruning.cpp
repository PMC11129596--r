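// Felsenstein-variant pruning for the multivariate Brownian likelihood.
//
// Post-order Gaussian message passing: every node carries a conditional
// mean vector m (k), a covariance S (k x k) and an accumulated log-density.
// Combining two messages (m1,S1), (m2,S2) at a node uses the exact
// information-filter update written in a form that tolerates singular
// individual messages (exact observations from sampled ancestors have
// S = 0) as long as S1 + S2 is positive definite:
//   acc += log N(m1 - m2; 0, S1 + S2)
//   A    = (S1 + S2)^{-1} S1
//   m    = m1 + A' (m2 - m1)
//   S    = S1 - S1 A   (symmetrized)
// Branches add w * Sigma to S (w = c_m * b * length, zero for the merged
// sampled-ancestor attachment); observations enter as messages (x, Verr).
// At the root the final message gives N(y0; m_root, S_root), or, with y0
// profiled, the density at its maximum y0hat = m_root.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// status: 0 ok, 1 singular covariance, 2 conflicting exact observations
// [[Rcpp::export]]
Rcpp::List prune_felsenstein_cpp(Rcpp::IntegerVector parent,
                                 Rcpp::IntegerVector porder,
                                 Rcpp::NumericVector wlen,
                                 Rcpp::IntegerVector obs,
                                 const arma::mat& Xt,   // k x n observations
                                 const arma::mat& Sigma,
                                 const arma::mat& Verr,
                                 const arma::vec& y0,
                                 double root_wvar) {
  const int N = parent.size();
  const int k = Sigma.n_rows;
  const bool ml = (y0.n_elem == 0);
  const bool has_verr = any(vectorise(abs(Verr)) > 0.0);

  mat dummy;
  if (!chol(dummy, Sigma))
    return Rcpp::List::create(Rcpp::Named("status") = 1,
                              Rcpp::Named("loglik") = NA_REAL,
                              Rcpp::Named("y0hat") = R_NilValue);

  std::vector<char> has(N, 0);
  std::vector<vec> M(N);
  std::vector<mat> S(N);
  double acc = 0.0;
  const double LOG2PI = std::log(2.0 * M_PI);

  // fold message (m2,S2) into the running message of node u
  auto fold = [&](int u, const vec& m2, const mat& s2) -> int {
    if (!has[u]) { M[u] = m2; S[u] = s2; has[u] = 1; return 0; }
    mat S12 = S[u] + s2;
    mat R;
    if (!chol(R, S12)) {
      // both messages exactly degenerate: allowed only if they agree
      if (norm(S12, "fro") < 1e-14) {
        return (norm(M[u] - m2, 2) < 1e-9) ? 3 : 2;
      }
      return 1;
    }
    vec d = M[u] - m2;
    vec z = solve(trimatl(R.t()), d);
    acc += -0.5 * (k * LOG2PI + 2.0 * sum(log(R.diag())) + dot(z, z));
    mat A = solve(S12, S[u]);          // (S1+S2)^{-1} S1
    M[u] = M[u] + A.t() * (m2 - M[u]);
    mat Snew = S[u] - S[u] * A;
    S[u] = 0.5 * (Snew + Snew.t());
    return 0;
  };

  int root = porder[porder.size() - 1];
  for (int idx = 0; idx < porder.size(); ++idx) {
    int u = porder[idx] - 1;             // to 0-based
    if (obs[u] > 0) {
      vec x = Xt.col(obs[u] - 1);
      mat s0 = has_verr ? Verr : zeros<mat>(k, k);
      int rc = fold(u, x, s0);
      if (rc == 1 || rc == 2)
        return Rcpp::List::create(Rcpp::Named("status") = rc,
                                  Rcpp::Named("loglik") = NA_REAL,
                                  Rcpp::Named("y0hat") = R_NilValue);
    }
    if (!has[u])
      Rcpp::stop("internal error: node without observation or children");
    if (u + 1 == root) continue;
    int p = parent[u] - 1;
    vec mu = M[u];
    mat su = S[u] + wlen[u] * Sigma;
    int rc = fold(p, mu, su);
    if (rc == 1 || rc == 2)
      return Rcpp::List::create(Rcpp::Named("status") = rc,
                                Rcpp::Named("loglik") = NA_REAL,
                                Rcpp::Named("y0hat") = R_NilValue);
  }

  int r = root - 1;
  if (root_wvar > 0.0) S[r] += root_wvar * Sigma;
  double loglik;
  vec y0hat = M[r];
  mat R;
  if (!chol(R, S[r])) {
    if (norm(S[r], "fro") < 1e-14) {
      // root state observed exactly
      if (ml) loglik = acc;
      else loglik = (norm(y0 - M[r], 2) < 1e-9) ? acc : -datum::inf;
    } else {
      return Rcpp::List::create(Rcpp::Named("status") = 1,
                                Rcpp::Named("loglik") = NA_REAL,
                                Rcpp::Named("y0hat") = R_NilValue);
    }
  } else if (ml) {
    loglik = acc - 0.5 * (k * LOG2PI + 2.0 * sum(log(R.diag())));
  } else {
    vec z = solve(trimatl(R.t()), y0 - M[r]);
    loglik = acc - 0.5 * (k * LOG2PI + 2.0 * sum(log(R.diag())) + dot(z, z));
  }
  return Rcpp::List::create(Rcpp::Named("status") = 0,
                            Rcpp::Named("loglik") = loglik,
                            Rcpp::Named("y0hat") = y0hat);
}
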