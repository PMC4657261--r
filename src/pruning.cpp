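// Felsenstein pruning on the coupled pair-state chain.
//
// The generator Q is eigendecomposed once per call (one call per likelihood
// evaluation during optimisation); each edge then propagates a partial-
// likelihood vector as V * (exp(lambda * t) .* (Vinv * L)), i.e. two small
// matrix-vector products instead of a matrix exponential. When the
// eigenbasis fails to reconstruct Q (defective or ill-conditioned case) the
// code falls back to scaling-and-squaring expmat per edge. Partials are
// rescaled per edge and the log scale accumulated to avoid underflow on
// large trees.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export(name = ".prune_loglik_cpp")]]
double prune_loglik_cpp(const arma::mat& Q,
                        const arma::imat& edge,      // postorder, cols: parent, child (1-based)
                        const arma::vec& edge_len,
                        const arma::ivec& tip_state, // per tip (1..ntip), 1-based state index
                        const arma::vec& root_dist,  // empty: use stationary of Q
                        const int n_tip,
                        const int root) {
  const uword m = Q.n_rows;

  vec pi;
  if (root_dist.n_elem == 0) {
    // stationary distribution: least squares on [Q^T; 1] pi = [0; 1]
    mat A(m + 1, m);
    A.rows(0, m - 1) = Q.t();
    A.row(m).ones();
    vec b(m + 1, fill::zeros);
    b(m) = 1.0;
    bool ok = solve(pi, A, b);
    if (!ok || pi.min() < -1e-8) return R_NegInf;
    pi.transform([](double v) { return v < 0.0 ? 0.0 : v; });
    pi /= accu(pi);
  } else {
    pi = root_dist;
  }

  const uword n_edge = edge.n_rows;
  const uword n_node = n_tip + n_tip - 1;  // rooted binary

  // eigen machinery with fallback
  cx_vec eval;
  cx_mat evec, vinv;
  bool use_eig = true;
  try {
    eig_gen(eval, evec, Q);
    vinv = inv(evec);
    double err = norm(real(evec * diagmat(eval) * vinv) - Q, "fro");
    if (!std::isfinite(err) || err > 1e-9 * (1.0 + norm(Q, "fro")))
      use_eig = false;
  } catch (...) {
    use_eig = false;
  }

  mat L(m, n_node, fill::ones);
  std::vector<bool> seen(n_node, false);
  for (int i = 0; i < n_tip; ++i) {
    L.col(i).zeros();
    L.col(i)(tip_state(i) - 1) = 1.0;
    seen[i] = true;
  }

  double logscale = 0.0;
  for (uword e = 0; e < n_edge; ++e) {
    const int parent = edge(e, 0) - 1;
    const int child = edge(e, 1) - 1;
    const double t = edge_len(e);
    vec w(m);
    if (t == 0.0) {
      w = L.col(child);         // P(0) = I exactly
    } else if (use_eig) {
      cx_vec z = vinv * cx_vec(L.col(child), vec(m, fill::zeros));
      z %= exp(eval * t);
      cx_vec wc = evec * z;
      w = real(wc);
    } else {
      mat P = expmat(Q * t);
      w = P * L.col(child);
    }
    w.transform([](double v) { return v < 0.0 ? 0.0 : v; });
    double mx = w.max();
    if (mx <= 0.0) return R_NegInf;
    w /= mx;
    logscale += std::log(mx);
    L.col(parent) %= w;
  }

  double lik = dot(pi, L.col(root - 1));
  if (lik <= 0.0) return R_NegInf;
  return std::log(lik) + logscale;
}
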