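#include <Rcpp.h>
#include <cmath>
#include "boys.h"

void boys_vec(int mmax, double x, double *F) {
  if (x < 0) Rcpp::stop("Boys function: negative argument");
  if (x < 1e-14) {
    for (int m = 0; m <= mmax; ++m) F[m] = 1.0 / (2 * m + 1) - x / (2 * m + 3);
    return;
  }
  const double ex = std::exp(-x);
  if (x <= 35.0) {
    // series for the top order, then stable downward recursion
    double term = 1.0 / (2 * mmax + 1), sum = term;
    int i = 0;
    while (term > sum * 1e-17 && i < 10000) {
      ++i;
      term *= 2.0 * x / (2 * mmax + 2 * i + 1);
      sum += term;
    }
    F[mmax] = ex * sum;
    for (int m = mmax; m > 0; --m)
      F[m - 1] = (2.0 * x * F[m] + ex) / (2 * m - 1);
  } else {
    F[0] = 0.5 * std::sqrt(M_PI / x);
    for (int m = 0; m < mmax; ++m)
      F[m + 1] = ((2 * m + 1) * F[m] - ex) / (2.0 * x);
  }
}

// [[Rcpp::export]]
Rcpp::NumericVector boys_cpp(int m, Rcpp::NumericVector x) {
  Rcpp::NumericVector out(x.size());
  std::vector<double> buf(m + 1);
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    boys_vec(m, x[i], buf.data());
    out[i] = buf[m];
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::NumericVector boys_table_cpp(int mmax, double x) {
  Rcpp::NumericVector out(mmax + 1);
  boys_vec(mmax, x, &out[0]);
  return out;
}
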