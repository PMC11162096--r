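#include <Rcpp.h>
using namespace Rcpp;

// Weighted pool-adjacent-violators on one sequence.
// Stack of blocks; each block carries its weighted mean and total weight.
static void pava_one(const double* x, const double* w, int J,
                     double* mean_buf, double* wt_buf, int* len_buf,
                     double* out) {
  int nb = 0;
  for (int j = 0; j < J; ++j) {
    double m = x[j], wt = w[j];
    int len = 1;
    while (nb > 0 && mean_buf[nb - 1] > m) {
      m = (mean_buf[nb - 1] * wt_buf[nb - 1] + m * wt) / (wt_buf[nb - 1] + wt);
      wt += wt_buf[nb - 1];
      len += len_buf[nb - 1];
      --nb;
    }
    mean_buf[nb] = m;
    wt_buf[nb] = wt;
    len_buf[nb] = len;
    ++nb;
  }
  int pos = 0;
  for (int b = 0; b < nb; ++b)
    for (int k = 0; k < len_buf[b]; ++k) out[pos++] = mean_buf[b];
}

//' Weighted isotonic regression (pool-adjacent-violators)
//'
//' Least-squares non-decreasing fit of \code{x} under positive weights
//' \code{w}. Internal workhorse; see \code{\link{pava}} for the checked
//' user-facing wrapper.
//'
//' @param x numeric vector to fit.
//' @param w positive weights, same length as \code{x}.
//' @return numeric vector, the non-decreasing fit.
//' @keywords internal
// [[Rcpp::export]]
NumericVector pava_fit(NumericVector x, NumericVector w) {
  int J = x.size();
  if (w.size() != J) stop("`x` and `w` must have the same length");
  NumericVector out(J);
  std::vector<double> mb(J), wb(J);
  std::vector<int> lb(J);
  pava_one(x.begin(), w.begin(), J, mb.data(), wb.data(), lb.data(),
           out.begin());
  return out;
}

//' Row-wise weighted isotonic regression of a draw matrix
//'
//' Applies weighted PAVA to every row of a T-by-J matrix of posterior draws
//' with a single fixed weight vector, as used to impose monotonicity across
//' doses draw by draw.
//'
//' @param x numeric matrix (draws in rows, doses in columns).
//' @param w positive weights of length \code{ncol(x)}.
//' @return matrix of the same dimension with every row non-decreasing.
//' @keywords internal
// [[Rcpp::export]]
NumericMatrix pava_rows_fit(NumericMatrix x, NumericVector w) {
  int T = x.nrow(), J = x.ncol();
  if (w.size() != J) stop("`w` must have length ncol(x)");
  NumericMatrix out(T, J);
  std::vector<double> row(J), fit(J), mb(J), wb(J);
  std::vector<int> lb(J);
  for (int t = 0; t < T; ++t) {
    for (int j = 0; j < J; ++j) row[j] = x(t, j);
    pava_one(row.data(), w.begin(), J, mb.data(), wb.data(), lb.data(),
             fit.data());
    for (int j = 0; j < J; ++j) out(t, j) = fit[j];
  }
  return out;
}
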