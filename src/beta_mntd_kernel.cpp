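#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Abundance-weighted between-community mean nearest taxon distance (beta-MNTD)
// for every pair of samples at once.
//
// comm: n_samples x n_taxa matrix of within-sample relative abundances
//       (each row sums to 1; zeros mark absent taxa)
// dist: n_taxa x n_taxa symmetric patristic distance matrix
//
// For a pair (a, b):
//   betaMNTD = 0.5 * [ sum_i f_a(i) * min_{j in b} d(i, j)
//                    + sum_j f_b(j) * min_{i in a} d(j, i) ]
// A taxon present in both samples has nearest-neighbour distance 0.
//
// The per-sample nearest-taxon map mmin(i, b) = min_{j in b} d(i, j) is shared
// across all pairs involving b, so the whole matrix costs
// O(n_samples * n_taxa * mean_richness) plus one dense product.
// [[Rcpp::export]]
arma::mat beta_mntd_kernel(const arma::mat& comm, const arma::mat& dist) {
  const arma::uword n = comm.n_rows;
  const arma::uword S = comm.n_cols;
  if (dist.n_rows != S || dist.n_cols != S)
    Rcpp::stop("distance matrix dimension does not match taxon count");

  arma::mat mmin(S, n);
  for (arma::uword b = 0; b < n; ++b) {
    arma::uvec occ = arma::find(comm.row(b) > 0.0);
    if (occ.n_elem == 0) Rcpp::stop("sample %d has no taxa", (int)(b + 1));
    mmin.col(b) = arma::min(dist.cols(occ), 1);
  }

  arma::mat T = comm * mmin;        // T(a,b) = sum_i f_a(i) * mmin(i, b)
  arma::mat M = 0.5 * (T + T.t());
  M.diag().zeros();
  return M;
}
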