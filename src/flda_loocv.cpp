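// Compiled kernel for the exhaustive search: leave-one-out cross-validated
// Fisher discriminant accuracy for a list of feature subsets of one
// (channel, window) feature matrix. Semantics mirror the R reference path
// (flda_fit / predict / loocv_accuracy) exactly.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

// [[Rcpp::export]]
Rcpp::NumericVector loocv_subsets_cpp(const arma::mat& X,
                                      const arma::ivec& y,
                                      Rcpp::List subsets,
                                      double ridge) {
  const arma::uword n = X.n_rows;
  Rcpp::NumericVector out(subsets.size());
  for (R_xlen_t s = 0; s < subsets.size(); ++s) {
    arma::uvec cols = Rcpp::as<arma::uvec>(subsets[s]) - 1;
    arma::mat Xs = X.cols(cols);
    if (!Xs.is_finite()) { out[s] = NA_REAL; continue; }
    const arma::uword d = Xs.n_cols;
    int correct = 0;
    bool failed = false;
    for (arma::uword i = 0; i < n && !failed; ++i) {
      arma::vec sum_a(d, arma::fill::zeros), sum_b(d, arma::fill::zeros);
      arma::mat Qa(d, d, arma::fill::zeros), Qb(d, d, arma::fill::zeros);
      arma::uword na = 0, nb = 0;
      for (arma::uword j = 0; j < n; ++j) {
        if (j == i) continue;
        arma::vec xj = Xs.row(j).t();
        if (y[j] == 0) { sum_a += xj; Qa += xj * xj.t(); ++na; }
        else           { sum_b += xj; Qb += xj * xj.t(); ++nb; }
      }
      if (na < 1 || nb < 1) { failed = true; break; }
      arma::vec ma = sum_a / na, mb = sum_b / nb;
      arma::mat Sw = Qa - double(na) * (ma * ma.t()) +
                     Qb - double(nb) * (mb * mb.t());
      Sw.diag() += ridge;
      arma::vec w;
      if (!arma::solve(w, Sw, ma - mb, arma::solve_opts::no_approx)) {
        failed = true; break;
      }
      double pa = arma::dot(w, ma), pb = arma::dot(w, mb);
      double thr = 0.5 * (pa + pb);
      double a_side = (pa > thr) ? 1.0 : ((pa < thr) ? -1.0 : 1.0);
      double proj = arma::dot(w, Xs.row(i).t());
      bool pred_a = (proj - thr) * a_side >= 0.0;
      bool is_a = (y[i] == 0);
      if (pred_a == is_a) ++correct;
    }
    out[s] = failed ? NA_REAL : double(correct) / double(n);
  }
  return out;
}
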