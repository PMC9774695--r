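#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Propose per-cow random effects from the exact Gaussian conditional given
// the longitudinal data and N(0, D) prior: P_i = D^-1 + sum_k Z'Z_ik/s2_k,
// rhs_i = sum_k Z'(y - X beta)_ik / s2_k, draw m_i + chol(P_i)^-1 z_i.
// Standard normals z are generated in R so the R RNG stream governs
// reproducibility.
// [[Rcpp::export]]
arma::mat propose_ranef(const arma::mat& Dinv,
                        const arma::vec& sigma2,
                        const Rcpp::List& ZtZ,
                        const Rcpp::List& Zty,
                        const Rcpp::List& ZtX,
                        const Rcpp::List& beta,
                        const Rcpp::List& blocks,
                        const arma::mat& z) {
  const int n = z.n_rows, q = z.n_cols, K = ZtZ.size();
  mat out(n, q);
  std::vector<mat> ZtZm(K), Ztym(K), ZtXm(K);
  std::vector<vec> betav(K);
  std::vector<uvec> blk(K);
  for (int k = 0; k < K; k++) {
    ZtZm[k] = Rcpp::as<mat>(ZtZ[k]);
    Ztym[k] = Rcpp::as<mat>(Zty[k]);
    ZtXm[k] = Rcpp::as<mat>(ZtX[k]);
    betav[k] = Rcpp::as<vec>(beta[k]);
    blk[k] = Rcpp::as<uvec>(blocks[k]) - 1;
  }
  for (int i = 0; i < n; i++) {
    mat P = Dinv;
    vec rhs(q, fill::zeros);
    for (int k = 0; k < K; k++) {
      const int qk = blk[k].n_elem;
      const int pk = betav[k].n_elem;
      mat zz = reshape(ZtZm[k].row(i).t(), qk, qk);
      mat zx = reshape(ZtXm[k].row(i).t(), qk, pk);
      P(blk[k], blk[k]) += zz / sigma2[k];
      rhs(blk[k]) = (Ztym[k].row(i).t() - zx * betav[k]) / sigma2[k];
    }
    mat U = chol(P);
    vec m = solve(trimatu(U), solve(trimatl(U.t()), rhs));
    out.row(i) = (m + solve(trimatu(U), z.row(i).t())).t();
  }
  return out;
}

// Row-wise dot products of a design block with per-cow coefficient rows:
// out[r] = dot(A.row(r), b.row(idx[r]-1)); used for the random-effect part
// of the association linear predictor at the quadrature nodes.
// [[Rcpp::export]]
arma::vec assoc_ranef(const arma::mat& A, const arma::mat& b,
                      const arma::uvec& idx) {
  const int N = A.n_rows;
  vec out(N);
  for (int r = 0; r < N; r++)
    out[r] = dot(A.row(r), b.row(idx[r] - 1));
  return out;
}
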