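#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward pass for a K-state HMM whose transition matrix
// varies with minute-of-day. logdens: T x K log emission densities (rows of
// zeros for missing observations marginalise them out). trans: K*K*1440
// array (from, to, minute), row-stochastic in 'to' at every minute; the
// transition from step t to t+1 uses the minute-of-day of step t. init:
// length-K initial distribution. minute: length-T integer minute-of-day
// (0..1439). Returns posterior state probabilities gamma (T x K), expected
// transition counts aggregated by minute-of-day (1440 x K*K, column-major
// in (from, to)), and the log-likelihood.
// [[Rcpp::export]]
List fb_pass(NumericMatrix logdens, NumericVector init, NumericVector trans,
             IntegerVector minute) {
  const int T = logdens.nrow(), K = logdens.ncol();
  NumericMatrix alpha(T, K), beta(T, K), gamma(T, K);
  NumericVector scale(T);
  NumericMatrix xi_agg(1440, K * K);

  // emission densities, renormalised per row for numerical safety
  NumericMatrix dens(T, K);
  for (int t = 0; t < T; ++t) {
    double mx = logdens(t, 0);
    for (int k = 1; k < K; ++k) if (logdens(t, k) > mx) mx = logdens(t, k);
    for (int k = 0; k < K; ++k) dens(t, k) = std::exp(logdens(t, k) - mx);
    scale[t] = mx;  // stash the shift; re-used below for the loglik
  }

  double loglik = 0.0;
  // forward
  double c0 = 0.0;
  for (int k = 0; k < K; ++k) { alpha(0, k) = init[k] * dens(0, k); c0 += alpha(0, k); }
  loglik += std::log(c0) + scale[0];
  for (int k = 0; k < K; ++k) alpha(0, k) /= c0;
  for (int t = 1; t < T; ++t) {
    const int m = minute[t - 1];
    double ct = 0.0;
    for (int j = 0; j < K; ++j) {
      double s = 0.0;
      for (int i = 0; i < K; ++i) s += alpha(t - 1, i) * trans[i + K * j + K * K * m];
      alpha(t, j) = s * dens(t, j);
      ct += alpha(t, j);
    }
    loglik += std::log(ct) + scale[t];
    for (int j = 0; j < K; ++j) alpha(t, j) /= ct;
    scale[t] = ct;  // now holds the forward scaling constant
  }

  // backward
  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    const int m = minute[t];
    for (int i = 0; i < K; ++i) {
      double s = 0.0;
      for (int j = 0; j < K; ++j)
        s += trans[i + K * j + K * K * m] * dens(t + 1, j) * beta(t + 1, j);
      beta(t, i) = s / scale[t + 1];
    }
  }

  // gamma and aggregated xi
  for (int t = 0; t < T; ++t) {
    double s = 0.0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); s += gamma(t, k); }
    for (int k = 0; k < K; ++k) gamma(t, k) /= s;
  }
  for (int t = 0; t + 1 < T; ++t) {
    const int m = minute[t];
    for (int i = 0; i < K; ++i) {
      for (int j = 0; j < K; ++j) {
        double x = alpha(t, i) * trans[i + K * j + K * K * m] *
                   dens(t + 1, j) * beta(t + 1, j) / scale[t + 1];
        xi_agg(m, i + K * j) += x;
      }
    }
  }

  return List::create(_["gamma"] = gamma, _["xi_by_minute"] = xi_agg,
                      _["loglik"] = loglik);
}
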