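// Batch spectral kernels for dense complex field matrices.
//
// Every column of a d x m matrix is an n x n complex field (d = n^2,
// column-major).  The hot path of the reconstruction loop is applying a
// frequency-diagonal operator (free-space transfer function, pupil) to every
// column; doing the 2D FFTs column-by-column in C++ keeps the working set in
// cache and avoids the large intermediate copies an R-level implementation
// needs.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Apply a 2D spectral filter to every column: col -> ifft2( H % fft2(col) ).
// H is the n x n transfer function in unshifted FFT order.
// [[Rcpp::export]]
arma::cx_mat col_spectral_apply(const arma::cx_mat& A, const arma::cx_mat& H,
                                const int n) {
  const uword d = A.n_rows, m = A.n_cols;
  if (d != uword(n) * uword(n) || H.n_rows != uword(n) || H.n_cols != uword(n))
    Rcpp::stop("col_spectral_apply: dimension mismatch");
  cx_mat out(d, m);
  for (uword j = 0; j < m; ++j) {
    const cx_mat f(const_cast<cx_double*>(A.colptr(j)), n, n, false, true);
    cx_mat g = ifft2(fft2(f) % H);
    std::memcpy(out.colptr(j), g.memptr(), sizeof(cx_double) * d);
  }
  return out;
}

// Unitary 2D DFT (or inverse) of every column, unshifted order.
// [[Rcpp::export]]
arma::cx_mat col_fft2(const arma::cx_mat& A, const int n, const bool inverse) {
  const uword d = A.n_rows, m = A.n_cols;
  if (d != uword(n) * uword(n))
    Rcpp::stop("col_fft2: dimension mismatch");
  const double s = std::sqrt(double(d));
  cx_mat out(d, m);
  for (uword j = 0; j < m; ++j) {
    const cx_mat f(const_cast<cx_double*>(A.colptr(j)), n, n, false, true);
    cx_mat g = inverse ? cx_mat(ifft2(f) * s) : cx_mat(fft2(f) / s);
    std::memcpy(out.colptr(j), g.memptr(), sizeof(cx_double) * d);
  }
  return out;
}

// Scale column j of A by v[j] (diagonal right-multiplication).
// [[Rcpp::export]]
arma::cx_mat col_scale(const arma::cx_mat& A, const arma::cx_vec& v) {
  if (v.n_elem != A.n_cols) Rcpp::stop("col_scale: length mismatch");
  cx_mat out = A;
  for (uword j = 0; j < out.n_cols; ++j) out.col(j) *= v(j);
  return out;
}

// Scale row i of A by v[i] (diagonal left-multiplication).
// [[Rcpp::export]]
arma::cx_mat row_scale(const arma::cx_mat& A, const arma::cx_vec& v) {
  if (v.n_elem != A.n_rows) Rcpp::stop("row_scale: length mismatch");
  cx_mat out = A;
  for (uword j = 0; j < out.n_cols; ++j) out.col(j) %= v;
  return out;
}
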