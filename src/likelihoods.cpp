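// Pruning-algorithm likelihood kernels used by the rate-heterogeneity
// rjMCMC and the correlated-evolution tests. Edges are passed 1-based in
// ape's orderings (postorder for pruning, cladewise for painting).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Brownian-motion log-likelihood with per-edge variance increments
// vl[e] = rate_e * length_e and a fixed root state m0.
// Edges must be in postorder. Exact multivariate-normal density.
// [[Rcpp::export(name = ".bm_pruning_cpp")]]
double bm_pruning_cpp(const IntegerMatrix edge, const NumericVector vl,
                      const int ntip, const int nnode,
                      const NumericVector tip_x, const double m0) {
  const int nn = ntip + nnode;
  std::vector<double> m(nn, 0.0), v(nn, 0.0);
  std::vector<int> seen(nn, 0);
  for (int i = 0; i < ntip; ++i) m[i] = tip_x[i];
  double ll = 0.0;
  const double LOG2PI = 1.837877066409345483560659472811;
  for (int e = 0; e < edge.nrow(); ++e) {
    const int p = edge(e, 0) - 1, c = edge(e, 1) - 1;
    const double tc = v[c] + vl[e];
    if (!seen[p]) {
      m[p] = m[c];
      v[p] = tc;
      seen[p] = 1;
    } else {
      const double s = v[p] + tc, d = m[p] - m[c];
      ll += -0.5 * (LOG2PI + std::log(s) + d * d / s);
      m[p] = (m[p] * tc + m[c] * v[p]) / s;
      v[p] = v[p] * tc / s;
    }
  }
  const int root = ntip; // ape convention: root = ntip + 1 (1-based)
  // NA root state requests the profile likelihood (root at its ML value,
  // which the pruning pass delivers as m[root])
  const double d = ISNAN(m0) ? 0.0 : m[root] - m0;
  if (v[root] <= 0) return R_NegInf;
  ll += -0.5 * (LOG2PI + std::log(v[root]) + d * d / v[root]);
  return ll;
}

// Per-edge rates implied by a shift configuration. Edges in cladewise
// order; shift_class[e] > 0 marks edge e as the start of that rate class,
// class 0 is the root class. Returns the class index of every edge.
// [[Rcpp::export(name = ".edge_classes_cpp")]]
IntegerVector edge_classes_cpp(const IntegerMatrix edge,
                               const IntegerVector shift_class,
                               const int ntip, const int nnode) {
  const int ne = edge.nrow();
  std::vector<int> node_class(ntip + nnode, 0);
  IntegerVector out(ne);
  for (int e = 0; e < ne; ++e) {
    const int p = edge(e, 0) - 1, c = edge(e, 1) - 1;
    int cl = node_class[p];
    if (shift_class[e] > 0) cl = shift_class[e];
    out[e] = cl;
    node_class[c] = cl;
  }
  return out;
}

// Joint 4-state CTMC log-likelihood for a pair of binary characters.
// States are 1 + 2*a + b (00, 01, 10, 11). Edges in postorder; tip
// states 0..3. Root weighted by root_probs. Scaled pruning.
// [[Rcpp::export(name = ".ctmc_pruning_cpp")]]
double ctmc_pruning_cpp(const IntegerMatrix edge, const NumericVector len,
                        const int ntip, const int nnode,
                        const IntegerVector tip_state,
                        const arma::mat Q, const arma::vec root_probs) {
  const int nn = ntip + nnode;
  arma::mat L(4, nn, arma::fill::ones);
  for (int i = 0; i < ntip; ++i) {
    L.col(i).zeros();
    L(tip_state[i], i) = 1.0;
  }
  std::vector<int> seen(nn, 0);
  double logscale = 0.0;
  // one eigendecomposition of Q gives every branch propagator; fall back
  // to per-branch Pade exponentials if Q is close to defective
  arma::cx_vec eval;
  arma::cx_mat evec, evinv;
  bool use_eig = arma::eig_gen(eval, evec, Q);
  if (use_eig) use_eig = arma::rcond(evec) > 1e-8 && arma::inv(evinv, evec);
  for (int e = 0; e < edge.nrow(); ++e) {
    const int p = edge(e, 0) - 1, c = edge(e, 1) - 1;
    arma::mat P;
    if (use_eig) {
      P = arma::real(evec * arma::diagmat(arma::exp(eval * len[e])) * evinv);
      P.elem(arma::find(P < 0)).zeros();
    } else {
      P = arma::expmat(Q * len[e]);
    }
    arma::vec contrib = P * L.col(c);
    if (!seen[p]) {
      L.col(p) = contrib;
      seen[p] = 1;
    } else {
      L.col(p) %= contrib;
    }
    const double mx = L.col(p).max();
    if (mx > 0 && mx < 1e-280) {
      L.col(p) /= mx;
      logscale += std::log(mx);
    }
  }
  const double lik = arma::dot(root_probs, L.col(ntip));
  if (lik <= 0) return R_NegInf;
  return std::log(lik) + logscale;
}
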