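// Iterative fragment-seeded TM-score search. Each seed superposes the two
// traces on a residue subset (Kabsch), then repeatedly re-superposes on the
// residue pairs closer than a shrinking distance cutoff; the best score seen
// under any visited transform is kept. Exhaustive seeding over contiguous
// fragments is quadratic in chain length, hence the compiled hot loop.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Proper rotation R and translation t minimizing ||P R^T + t - Q||_F.
static void kabsch(const arma::mat& P, const arma::mat& Q,
                   arma::mat& R, arma::rowvec& t) {
  arma::rowvec cp = arma::mean(P, 0), cq = arma::mean(Q, 0);
  arma::mat H = (P.each_row() - cp).t() * (Q.each_row() - cq);
  arma::mat U, V;
  arma::vec s;
  arma::svd(U, s, V, H);
  arma::mat D = arma::eye(3, 3);
  if (arma::det(V * U.t()) < 0) D(2, 2) = -1.0;
  R = V * D * U.t();
  t = cq - cp * R.t();
}

// [[Rcpp::export]]
double tm_search_cpp(const arma::mat& A, const arma::mat& B,
                     const List& seeds, double d0, double L_norm,
                     const arma::vec& schedule, int max_iter) {
  const arma::uword n = A.n_rows;
  double best = 0.0;
  const double d0sq = d0 * d0;
  for (R_xlen_t sidx = 0; sidx < seeds.size(); ++sidx) {
    arma::uvec sel = as<arma::uvec>(seeds[sidx]) - 1;  // 1-based from R
    for (int iter = 1; iter <= max_iter; ++iter) {
      if (sel.n_elem < 3) break;
      arma::mat R;
      arma::rowvec t;
      kabsch(A.rows(sel), B.rows(sel), R, t);
      arma::mat moved = A * R.t();
      moved.each_row() += t;
      arma::vec dsq = arma::sum(arma::square(moved - B), 1);
      double score = arma::accu(1.0 / (1.0 + dsq / d0sq)) / L_norm;
      if (score > best) best = score;
      int si = iter <= (int)schedule.n_elem ? iter - 1
                                            : (int)schedule.n_elem - 1;
      double cut = schedule(si);
      arma::uvec nxt = arma::find(dsq < cut * cut);
      double dmax = std::sqrt(dsq.max());
      while (nxt.n_elem < 3 && cut < dmax + 1.0) {
        cut += 0.5;
        nxt = arma::find(dsq < cut * cut);
      }
      bool stable = (iter >= (int)schedule.n_elem) &&
                    (nxt.n_elem == sel.n_elem) &&
                    arma::all(nxt == sel);
      if (stable) break;
      sel = nxt;
    }
    if (best >= (double)n / L_norm - 1e-15) break;  // cannot improve further
  }
  return best;
}
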