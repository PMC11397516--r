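// Orthogonal matching pursuit for block sparse coding.  Atoms are unit-norm
// rows of D; each block (row of X) is greedily decomposed until its relative
// residual drops below `tol` or `max_sparsity` atoms are in use.  The
// coefficients of the selected atoms are re-solved by least squares at every
// step, so residual norms are non-increasing and no atom is picked twice.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;
using Rcpp::Named;

// [[Rcpp::export(name = ".omp_encode_batch")]]
List omp_encode_batch(const arma::mat& X, const arma::mat& D,
                      int max_sparsity, double tol) {
  const uword n = X.n_rows, K = D.n_rows;
  if (D.n_cols != X.n_cols)
    Rcpp::stop("block dimension (%d) does not match atom dimension (%d)",
               (int)X.n_cols, (int)D.n_cols);
  const mat G = D * D.t();                    // Gram matrix, K x K
  std::vector<int> ti, tj;
  std::vector<double> tv;
  vec relres(n, fill::zeros);
  for (uword b = 0; b < n; ++b) {
    const vec x = X.row(b).t();
    const double nx = norm(x);
    if (nx == 0.0) { relres(b) = 0.0; continue; }
    const vec Dx = D * x;                     // correlations with the block
    vec r = x;
    uvec sel;
    vec coef;
    for (int it = 0; it < max_sparsity; ++it) {
      vec corr = abs(D * r);
      if (!sel.is_empty()) corr.elem(sel).zeros();
      const uword k = corr.index_max();
      if (corr(k) < 1e-12 * nx) break;        // nothing left to explain
      sel.resize(sel.n_elem + 1);
      sel(sel.n_elem - 1) = k;
      coef = solve(G.submat(sel, sel), Dx.elem(sel),
                   solve_opts::likely_sympd);
      r = x - D.rows(sel).t() * coef;
      if (norm(r) <= tol * nx) break;
    }
    relres(b) = norm(r) / nx;
    for (uword s = 0; s < sel.n_elem; ++s) {
      ti.push_back((int)b + 1);
      tj.push_back((int)sel(s) + 1);
      tv.push_back(coef(s));
    }
  }
  return List::create(Named("i") = ti, Named("j") = tj, Named("x") = tv,
                      Named("relres") = relres,
                      Named("nblocks") = (int)n, Named("natoms") = (int)K);
}
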