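#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for one trajectory under a K-state Gaussian HMM
// with shared variance. Emissions are computed in log space and rescaled
// per frame so no probability can underflow for any trajectory length.
//
// Returns gamma (T x K state posteriors), xi summed over frames (K x K
// expected transition counts), and the total log-likelihood.
// [[Rcpp::export]]
List cpp_forward_backward(NumericVector x, NumericVector means, double sigma2,
                          NumericMatrix A, NumericVector pi0) {
  const int T = x.size(), K = means.size();
  const double lognorm = -0.5 * std::log(2.0 * M_PI * sigma2);
  NumericMatrix b(T, K);       // scaled emission likelihoods
  NumericVector bmax(T);       // per-frame log-scale factors
  for (int t = 0; t < T; ++t) {
    double m = R_NegInf;
    for (int k = 0; k < K; ++k) {
      double d = x[t] - means[k];
      double lb = lognorm - 0.5 * d * d / sigma2;
      b(t, k) = lb;
      if (lb > m) m = lb;
    }
    bmax[t] = m;
    for (int k = 0; k < K; ++k) b(t, k) = std::exp(b(t, k) - m);
  }

  NumericMatrix alpha(T, K), beta(T, K);
  NumericVector c(T);
  double loglik = 0.0;
  for (int k = 0; k < K; ++k) alpha(0, k) = pi0[k] * b(0, k);
  c[0] = 0.0;
  for (int k = 0; k < K; ++k) c[0] += alpha(0, k);
  for (int k = 0; k < K; ++k) alpha(0, k) /= c[0];
  loglik += std::log(c[0]) + bmax[0];
  for (int t = 1; t < T; ++t) {
    double ct = 0.0;
    for (int j = 0; j < K; ++j) {
      double s = 0.0;
      for (int i = 0; i < K; ++i) s += alpha(t - 1, i) * A(i, j);
      double a = s * b(t, j);
      alpha(t, j) = a;
      ct += a;
    }
    c[t] = ct;
    for (int j = 0; j < K; ++j) alpha(t, j) /= ct;
    loglik += std::log(ct) + bmax[t];
  }

  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int i = 0; i < K; ++i) {
      double s = 0.0;
      for (int j = 0; j < K; ++j) s += A(i, j) * b(t + 1, j) * beta(t + 1, j);
      beta(t, i) = s / c[t + 1];
    }
  }

  NumericMatrix gamma(T, K);
  for (int t = 0; t < T; ++t) {
    double s = 0.0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); s += gamma(t, k); }
    for (int k = 0; k < K; ++k) gamma(t, k) /= s;
  }

  NumericMatrix xi(K, K);
  for (int t = 0; t + 1 < T; ++t) {
    double s = 0.0;
    for (int i = 0; i < K; ++i)
      for (int j = 0; j < K; ++j)
        s += alpha(t, i) * A(i, j) * b(t + 1, j) * beta(t + 1, j);
    for (int i = 0; i < K; ++i)
      for (int j = 0; j < K; ++j)
        xi(i, j) += alpha(t, i) * A(i, j) * b(t + 1, j) * beta(t + 1, j) / s;
  }

  return List::create(_["gamma"] = gamma, _["xi"] = xi, _["loglik"] = loglik);
}

// Viterbi decoding in log space. Ties at every argmax are broken toward the
// lower state index (strict > comparison keeps the first maximum).
// [[Rcpp::export]]
List cpp_viterbi(NumericVector x, NumericVector means, double sigma2,
                 NumericMatrix A, NumericVector pi0) {
  const int T = x.size(), K = means.size();
  const double lognorm = -0.5 * std::log(2.0 * M_PI * sigma2);
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  auto logb = [&](int t, int k) {
    double d = x[t] - means[k];
    return lognorm - 0.5 * d * d / sigma2;
  };
  NumericMatrix logA(K, K);
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j)
      logA(i, j) = A(i, j) > 0 ? std::log(A(i, j)) : R_NegInf;
  for (int k = 0; k < K; ++k)
    delta(0, k) = (pi0[k] > 0 ? std::log(pi0[k]) : R_NegInf) + logb(0, k);
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < K; ++j) {
      double best = R_NegInf;
      int arg = 0;
      for (int i = 0; i < K; ++i) {
        double v = delta(t - 1, i) + logA(i, j);
        if (v > best) { best = v; arg = i; }
      }
      delta(t, j) = best + logb(t, j);
      psi(t, j) = arg;
    }
  }
  IntegerVector path(T);
  double best = R_NegInf;
  int arg = 0;
  for (int k = 0; k < K; ++k)
    if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  path[T - 1] = arg;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  return List::create(_["path"] = path, _["loglik"] = best);
}
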