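#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Weighted elastic-net solution path by cyclic coordinate descent with
// warm starts along a decreasing lambda sequence.
//
// Objective: (1/(2n)) ||y - X b||^2
//            + lambda * ( xi * sum_j theta_j |b_j|
//                         + (1 - xi)/2 * sum_j b_j^2 )
// theta_j down-weights the l1 penalty of predictors with prior
// knowledge; the l2 term is unmodified. Works on the Gram matrices only.
//
// [[Rcpp::export]]
arma::mat men_cd_path(const arma::mat& XtX, const arma::vec& Xty,
                      const double n, const arma::vec& theta,
                      const double xi, const arma::vec& lambda,
                      const double tol = 1e-7,
                      const int max_sweeps = 100000) {
  const uword p = Xty.n_elem;
  const uword nlam = lambda.n_elem;
  mat path(p, nlam, fill::zeros);
  vec b(p, fill::zeros);
  const vec diag_n = XtX.diag() / n;

  for (uword l = 0; l < nlam; ++l) {
    const double lam = lambda(l);
    for (int sweep = 0; sweep < max_sweeps; ++sweep) {
      double max_delta = 0.0;
      for (uword j = 0; j < p; ++j) {
        // partial residual correlation with predictor j
        double rho = Xty(j) - dot(XtX.row(j), b) + XtX(j, j) * b(j);
        rho /= n;
        const double thr = lam * xi * theta(j);
        double bj = 0.0;
        if (rho > thr)       bj = (rho - thr);
        else if (rho < -thr) bj = (rho + thr);
        bj /= (diag_n(j) + lam * (1.0 - xi));
        const double delta = std::abs(bj - b(j));
        if (delta > max_delta) max_delta = delta;
        b(j) = bj;
      }
      if (max_delta < tol) break;
    }
    path.col(l) = b;  // warm start for the next lambda
  }
  return path;
}
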