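#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Steady-state initial state of a direct-form-II-transposed IIR filter for a
// unit-step input, so forward/backward passes start transient-free.
static vec lfilter_zi(const vec &b, const vec &a) {
  const uword n = std::max(a.n_elem, b.n_elem);
  vec av = zeros<vec>(n), bv = zeros<vec>(n);
  av.head(a.n_elem) = a;
  bv.head(b.n_elem) = b;
  bv /= av(0);
  av /= av(0);
  mat A(n - 1, n - 1, fill::zeros);
  for (uword i = 0; i < n - 1; ++i) A(i, 0) = -av(i + 1);
  for (uword i = 0; i + 1 < n - 1; ++i) A(i, i + 1) = 1.0;
  vec B = bv.subvec(1, n - 1) - av.subvec(1, n - 1) * bv(0);
  return solve(eye<mat>(n - 1, n - 1) - A, B);
}

// Direct-form-II-transposed filter with initial state z (modified in place).
static vec lfilter(const vec &b, const vec &a, const vec &x, vec z) {
  const uword n = std::max(a.n_elem, b.n_elem);
  vec av = zeros<vec>(n), bv = zeros<vec>(n);
  av.head(a.n_elem) = a;
  bv.head(b.n_elem) = b;
  bv /= av(0);
  av /= av(0);
  vec y(x.n_elem);
  for (uword m = 0; m < x.n_elem; ++m) {
    const double xm = x(m);
    const double ym = bv(0) * xm + (n > 1 ? z(0) : 0.0);
    for (uword i = 0; i + 1 < n - 1; ++i)
      z(i) = bv(i + 1) * xm + z(i + 1) - av(i + 1) * ym;
    if (n > 1) z(n - 2) = bv(n - 1) * xm - av(n - 1) * ym;
    y(m) = ym;
  }
  return y;
}

static vec filtfilt_one(const vec &b, const vec &a, const vec &x, uword padlen,
                        const vec &zi) {
  const uword n = x.n_elem;
  const uword p = std::min(padlen, n - 1);
  vec ext(n + 2 * p);
  for (uword i = 0; i < p; ++i) ext(i) = 2.0 * x(0) - x(p - i);
  ext.subvec(p, p + n - 1) = x;
  for (uword i = 0; i < p; ++i) ext(p + n + i) = 2.0 * x(n - 1) - x(n - 2 - i);
  vec y = lfilter(b, a, ext, zi * ext(0));
  y = reverse(y);
  y = lfilter(b, a, y, zi * y(0));
  y = reverse(y);
  return y.subvec(p, p + n - 1);
}

//' @noRd
// [[Rcpp::export(name = ".bc_filtfilt_mat")]]
arma::mat bc_filtfilt_mat(const arma::vec &b, const arma::vec &a,
                          const arma::mat &x, const int padlen) {
  const vec zi = lfilter_zi(b, a);
  mat out(x.n_rows, x.n_cols);
  for (uword j = 0; j < x.n_cols; ++j)
    out.col(j) = filtfilt_one(b, a, x.col(j), (uword)padlen, zi);
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".bc_filter_causal")]]
arma::vec bc_filter_causal(const arma::vec &b, const arma::vec &a,
                           const arma::vec &x) {
  const vec zi = lfilter_zi(b, a);
  return lfilter(b, a, x, zi * x(0));
}
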