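#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Scaled forward-backward pass (Rabiner scaling) for a Gaussian-emission
// HMM over a list of observation sequences sharing one model.  Missing
// observations (NA) contribute a flat emission likelihood.  Returns the
// total log-likelihood and the accumulated sufficient statistics for one
// EM M-step.
// [[Rcpp::export]]
List hmm_estep(List xs, NumericVector mu, NumericVector sigma,
               NumericMatrix A, NumericVector pi0) {
  const int K = mu.size();
  double loglik = 0.0;
  NumericVector g1(K), g_obs(K), gx(K), gx2(K);
  NumericMatrix xi(K, K);
  const double LOG2PI = std::log(2.0 * M_PI);

  for (int s = 0; s < xs.size(); ++s) {
    NumericVector x = xs[s];
    const int T = x.size();
    if (T == 0) continue;
    NumericMatrix b(T, K), alpha(T, K), beta(T, K);
    NumericVector c(T);
    LogicalVector miss(T);
    for (int t = 0; t < T; ++t) {
      miss[t] = NumericVector::is_na(x[t]);
      for (int k = 0; k < K; ++k) {
        if (miss[t]) { b(t, k) = 1.0; continue; }
        double z = (x[t] - mu[k]) / sigma[k];
        double lb = -0.5 * (z * z + LOG2PI) - std::log(sigma[k]);
        b(t, k) = std::exp(lb);
        if (b(t, k) < 1e-300) b(t, k) = 1e-300;
      }
    }
    double cs = 0.0;
    for (int k = 0; k < K; ++k) { alpha(0, k) = pi0[k] * b(0, k); cs += alpha(0, k); }
    c[0] = cs;
    for (int k = 0; k < K; ++k) alpha(0, k) /= cs;
    for (int t = 1; t < T; ++t) {
      cs = 0.0;
      for (int k = 0; k < K; ++k) {
        double a = 0.0;
        for (int j = 0; j < K; ++j) a += alpha(t - 1, j) * A(j, k);
        alpha(t, k) = a * b(t, k);
        cs += alpha(t, k);
      }
      c[t] = cs;
      for (int k = 0; k < K; ++k) alpha(t, k) /= cs;
    }
    for (int t = 0; t < T; ++t) loglik += std::log(c[t]);

    for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
    for (int t = T - 2; t >= 0; --t)
      for (int k = 0; k < K; ++k) {
        double bs = 0.0;
        for (int j = 0; j < K; ++j) bs += A(k, j) * b(t + 1, j) * beta(t + 1, j);
        beta(t, k) = bs / c[t + 1];
      }

    // gamma(t,k) = alpha*beta sums to 1 under this scaling
    for (int t = 0; t < T; ++t)
      for (int k = 0; k < K; ++k) {
        double g = alpha(t, k) * beta(t, k);
        if (t == 0) g1[k] += g;
        if (!miss[t]) {
          g_obs[k] += g;
          gx[k] += g * x[t];
          gx2[k] += g * x[t] * x[t];
        }
      }
    for (int t = 0; t < T - 1; ++t)
      for (int j = 0; j < K; ++j)
        for (int k = 0; k < K; ++k)
          xi(j, k) += alpha(t, j) * A(j, k) * b(t + 1, k) * beta(t + 1, k) /
            c[t + 1];
  }
  return List::create(_["loglik"] = loglik, _["g1"] = g1,
                      _["g_obs"] = g_obs, _["gx"] = gx, _["gx2"] = gx2,
                      _["xi"] = xi);
}

// Viterbi decoding (log space).  Ties are broken toward the lowest state
// index.  Missing observations contribute log-emission 0 for every state.
// [[Rcpp::export]]
IntegerVector hmm_viterbi(NumericVector x, NumericVector mu,
                          NumericVector sigma, NumericMatrix A,
                          NumericVector pi0) {
  const int K = mu.size(), T = x.size();
  IntegerVector path(T);
  if (T == 0) return path;
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  const double LOG2PI = std::log(2.0 * M_PI);
  const double NEG_INF = -std::numeric_limits<double>::infinity();

  auto logb = [&](int t, int k) -> double {
    if (NumericVector::is_na(x[t])) return 0.0;
    double z = (x[t] - mu[k]) / sigma[k];
    return -0.5 * (z * z + LOG2PI) - std::log(sigma[k]);
  };
  for (int k = 0; k < K; ++k)
    delta(0, k) = (pi0[k] > 0 ? std::log(pi0[k]) : NEG_INF) + logb(0, k);
  for (int t = 1; t < T; ++t)
    for (int k = 0; k < K; ++k) {
      double best = NEG_INF;
      int arg = 0;
      for (int j = 0; j < K; ++j) {
        double lA = A(j, k) > 0 ? std::log(A(j, k)) : NEG_INF;
        double v = delta(t - 1, j) + lA;
        if (v > best) { best = v; arg = j; }   // strict: lowest j wins ties
      }
      delta(t, k) = best + logb(t, k);
      psi(t, k) = arg;
    }
  double best = NEG_INF;
  int arg = 0;
  for (int k = 0; k < K; ++k)
    if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  path[T - 1] = arg;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  return path + 1;   // 1-based state indices
}
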