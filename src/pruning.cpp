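// Felsenstein pruning on a rooted binary tree with per-edge rate matrices
// (HB) or a single shared matrix (NR), discrete-gamma rate categories and
// per-pattern log rescaling.  Matrix exponentials via arma::expmat.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// edge: nEdge x 2 integer matrix (parent, child), POSTORDER (children first),
//       1-based node ids; tips are 1..nTip, all ids <= nNodeTotal.
// tip_part: 4 x nPat x nTip cube of tip state indicators.
// Qs: 4 x 4 x nEdge (per-edge, already normalized) or 4 x 4 x 1 (shared).
// elen: branch length per edge row; rates: K category rates;
// root_dist: length-4 root distribution; weights: pattern weights.
// [[Rcpp::export]]
double prune_loglik_cpp(const arma::imat& edge, int n_tip, int n_node_total,
                        int root, const arma::cube& tip_part,
                        const arma::vec& weights, const arma::cube& Qs,
                        const arma::vec& elen, const arma::vec& rates,
                        const arma::vec& root_dist) {
  const uword n_pat = tip_part.n_cols;
  const uword n_edge = edge.n_rows;
  const uword K = rates.n_elem;
  const bool shared_Q = (Qs.n_slices == 1);
  if (n_pat == 0) return 0.0;

  mat per_cat(n_pat, K);  // per-pattern log-likelihood by category

  cube part(4, n_pat, n_node_total);
  rowvec logsc(n_pat);
  std::vector<int> touched(n_node_total + 1);

  for (uword k = 0; k < K; ++k) {
    logsc.zeros();
    std::fill(touched.begin(), touched.end(), 0);
    for (uword e = 0; e < n_edge; ++e) {
      const int par = edge(e, 0), ch = edge(e, 1);
      const mat& Q = shared_Q ? Qs.slice(0) : Qs.slice(e);
      mat P = expmat(Q * (elen(e) * rates(k)));
      const mat& cpart = (ch <= n_tip) ? tip_part.slice(ch - 1)
                                       : part.slice(ch - 1);
      mat M = P * cpart;  // 4 x nPat contribution of this child
      // rescale per pattern to avoid underflow, tracking log offsets
      rowvec mx = max(M, 0);
      for (uword p = 0; p < n_pat; ++p) {
        if (mx(p) <= 0.0) { logsc(p) = -datum::inf; mx(p) = 1.0; }
        else logsc(p) += std::log(mx(p));
      }
      M.each_row() /= mx;
      if (!touched[par]) { part.slice(par - 1) = M; touched[par] = 1; }
      else part.slice(par - 1) %= M;
    }
    rowvec site = root_dist.t() * part.slice(root - 1);
    for (uword p = 0; p < n_pat; ++p)
      per_cat(p, k) = (site(p) > 0.0 && std::isfinite(logsc(p)))
                        ? std::log(site(p)) + logsc(p) : -datum::inf;
  }

  // mix categories with equal weight 1/K via log-sum-exp, then weight
  double total = 0.0;
  const double logK = std::log((double) K);
  for (uword p = 0; p < n_pat; ++p) {
    double m = per_cat.row(p).max();
    double ll;
    if (!std::isfinite(m)) ll = -datum::inf;
    else {
      double s = 0.0;
      for (uword k = 0; k < K; ++k) s += std::exp(per_cat(p, k) - m);
      ll = m + std::log(s) - logK;
    }
    total += weights(p) * ll;
  }
  return total;
}
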