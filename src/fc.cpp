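// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Maximum normalized cross-correlation between every pair of rows of X over
// integer-sample lags in [-max_lag, max_lag]. At lag k >= 0, row i shifted
// by k is correlated with row j over the overlapping samples only, with the
// overlap's own means and standard deviations (Pearson on the overlap).
// Cross sums come from one FFT per row plus one inverse FFT per pair;
// windowed means/variances come from prefix sums. Lags whose overlap has
// (numerically) zero variance in either series are skipped; a pair with no
// valid lag gets value 0 and a flag. absolute = true maximizes |r| but
// returns the signed value at the maximizing lag. Ties break toward the
// most negative lag (scan order).
// [[Rcpp::export]]
List fc_max_xcorr_cpp(const arma::mat& X, int max_lag, bool absolute) {
  const int n = X.n_rows;
  const int T = X.n_cols;
  if (max_lag >= T) stop("max_lag must be smaller than the series length");

  int N = 1;
  while (N < 2 * T) N <<= 1;

  arma::cx_mat F(N, n);
  arma::mat P1(T + 1, n, arma::fill::zeros), P2(T + 1, n, arma::fill::zeros);
  for (int j = 0; j < n; ++j) {
    arma::vec pad(N, arma::fill::zeros);
    for (int t = 0; t < T; ++t) {
      const double v = X(j, t);
      pad(t) = v;
      P1(t + 1, j) = P1(t, j) + v;
      P2(t + 1, j) = P2(t, j) + v * v;
    }
    F.col(j) = arma::fft(pad);
  }

  NumericMatrix vals(n, n), lags(n, n);
  LogicalMatrix flags(n, n);
  for (int i = 0; i < n; ++i) vals(i, i) = 1.0;

  // a window variance this small relative to the window's energy is
  // indistinguishable from cancellation error in the prefix sums
  const double rel_eps = 1e-11;
  const double abs_eps = 1e-30;

  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      arma::cx_vec prod = F.col(i) % arma::conj(F.col(j));
      arma::vec cc = arma::real(arma::ifft(prod));
      bool any = false;
      double best_crit = 0.0, best_r = 0.0;
      int best_lag = 0;
      for (int k = -max_lag; k <= max_lag; ++k) {
        const int no = T - std::abs(k);
        const double S = (k >= 0) ? cc(k) : cc(N + k);
        double sx, sx2, sy, sy2;
        if (k >= 0) {  // x_i[(k+1)..T] vs x_j[1..(T-k)]
          sx = P1(T, i) - P1(k, i);
          sx2 = P2(T, i) - P2(k, i);
          sy = P1(T - k, j);
          sy2 = P2(T - k, j);
        } else {  // x_i[1..(T+k)] vs x_j[(1-k)..T]
          sx = P1(T + k, i);
          sx2 = P2(T + k, i);
          sy = P1(T, j) - P1(-k, j);
          sy2 = P2(T, j) - P2(-k, j);
        }
        const double vx = sx2 - sx * sx / no;
        const double vy = sy2 - sy * sy / no;
        if (vx <= rel_eps * sx2 + abs_eps || vy <= rel_eps * sy2 + abs_eps)
          continue;
        double r = (S - sx * sy / no) / std::sqrt(vx * vy);
        if (r > 1.0) r = 1.0;
        else if (r < -1.0) r = -1.0;
        const double crit = absolute ? std::fabs(r) : r;
        if (!any || crit > best_crit) {
          any = true;
          best_crit = crit;
          best_r = r;
          best_lag = k;
        }
      }
      if (any) {
        vals(i, j) = vals(j, i) = best_r;
        lags(i, j) = best_lag;
        lags(j, i) = -best_lag;
      } else {
        flags(i, j) = flags(j, i) = true;
      }
    }
  }

  return List::create(_["values"] = vals, _["lags"] = lags,
                      _["flags"] = flags);
}
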