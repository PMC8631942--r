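#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward pass for a K-state Gaussian-emission HMM on one
// trajectory. Returns log-likelihood, posterior state probabilities
// (gamma, T x K) and summed transition posteriors (xi_sum, K x K).
// [[Rcpp::export]]
List fb_gauss(NumericVector y, NumericVector mu, NumericVector sigma,
              NumericMatrix A, NumericVector pi0) {
  const int T = y.size(), K = mu.size();
  NumericMatrix b(T, K), alpha(T, K), beta(T, K), gamma(T, K);
  NumericVector c(T);
  const double SQRT2PI = 2.5066282746310002;
  for (int t = 0; t < T; ++t)
    for (int k = 0; k < K; ++k) {
      double z = (y[t] - mu[k]) / sigma[k];
      double d = std::exp(-0.5 * z * z) / (sigma[k] * SQRT2PI);
      b(t, k) = d > 1e-300 ? d : 1e-300;
    }
  // forward
  double s = 0.0;
  for (int k = 0; k < K; ++k) { alpha(0, k) = pi0[k] * b(0, k); s += alpha(0, k); }
  c[0] = s;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s;
  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int k = 0; k < K; ++k) {
      double a = 0.0;
      for (int j = 0; j < K; ++j) a += alpha(t - 1, j) * A(j, k);
      alpha(t, k) = a * b(t, k);
      s += alpha(t, k);
    }
    c[t] = s;
    for (int k = 0; k < K; ++k) alpha(t, k) /= s;
  }
  // backward
  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int k = 0; k < K; ++k) {
      double a = 0.0;
      for (int j = 0; j < K; ++j) a += A(k, j) * b(t + 1, j) * beta(t + 1, j);
      beta(t, k) = a / c[t + 1];
    }
  }
  NumericMatrix xi_sum(K, K);
  for (int t = 0; t < T; ++t) {
    double g = 0.0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); g += gamma(t, k); }
    for (int k = 0; k < K; ++k) gamma(t, k) /= g;
  }
  for (int t = 0; t < T - 1; ++t) {
    double norm = 0.0;
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k)
        norm += alpha(t, j) * A(j, k) * b(t + 1, k) * beta(t + 1, k);
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k)
        xi_sum(j, k) += alpha(t, j) * A(j, k) * b(t + 1, k) * beta(t + 1, k) / norm;
  }
  double ll = 0.0;
  for (int t = 0; t < T; ++t) ll += std::log(c[t]);
  return List::create(_["loglik"] = ll, _["gamma"] = gamma, _["xi_sum"] = xi_sum);
}

// Viterbi decoding; ties broken toward the lower state index (UNBOUND).
// Returns 1-based state path and the joint log-probability of the path.
// [[Rcpp::export]]
List viterbi_gauss(NumericVector y, NumericVector mu, NumericVector sigma,
                   NumericMatrix A, NumericVector pi0) {
  const int T = y.size(), K = mu.size();
  NumericMatrix logb(T, K), delta(T, K);
  IntegerMatrix psi(T, K);
  const double LOG2PI = 1.8378770664093453;
  for (int t = 0; t < T; ++t)
    for (int k = 0; k < K; ++k) {
      double z = (y[t] - mu[k]) / sigma[k];
      logb(t, k) = -0.5 * (z * z + LOG2PI) - std::log(sigma[k]);
    }
  for (int k = 0; k < K; ++k)
    delta(0, k) = std::log(std::max(pi0[k], 1e-300)) + logb(0, k);
  for (int t = 1; t < T; ++t)
    for (int k = 0; k < K; ++k) {
      int best = 0;
      double bv = delta(t - 1, 0) + std::log(std::max(A(0, k), 1e-300));
      for (int j = 1; j < K; ++j) {
        double v = delta(t - 1, j) + std::log(std::max(A(j, k), 1e-300));
        if (v > bv) { bv = v; best = j; }  // strict: ties keep lower index
      }
      delta(t, k) = bv + logb(t, k);
      psi(t, k) = best;
    }
  IntegerVector path(T);
  int last = 0;
  double bv = delta(T - 1, 0);
  for (int k = 1; k < K; ++k)
    if (delta(T - 1, k) > bv) { bv = delta(T - 1, k); last = k; }
  path[T - 1] = last + 1;
  for (int t = T - 2; t >= 0; --t) {
    last = psi(t + 1, last);
    path[t] = last + 1;
  }
  return List::create(_["path"] = path, _["logprob"] = bv);
}
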