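#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gaussian emission density with a hard floor to keep the scaled
// forward-backward recursion defined for outlier frames.
static inline double gdens(double x, double mu, double sigma) {
  double z = (x - mu) / sigma;
  double d = std::exp(-0.5 * z * z) / (sigma * 2.5066282746310002);
  return d > 1e-300 ? d : 1e-300;
}

// One E-step (scaled forward-backward) for a single trace under a shared
// 1-D Gaussian-emission HMM. Returns the log-likelihood and the sufficient
// statistics needed for the pooled M-step:
//   S0[k]  = sum_t gamma_t(k)
//   S1[k]  = sum_t gamma_t(k) * x_t
//   S2[k]  = sum_t gamma_t(k) * x_t^2
//   Xi[i,j]= sum_t xi_t(i,j)
//   G1[k]  = gamma_1(k)
// [[Rcpp::export]]
List hmm_estep(NumericVector obs, NumericVector mu, NumericVector sigma,
               NumericMatrix A, NumericVector pi0) {
  const int T = obs.size(), K = mu.size();
  NumericMatrix alpha(T, K), beta(T, K), B(T, K);
  NumericVector c(T);

  for (int t = 0; t < T; ++t)
    for (int k = 0; k < K; ++k)
      B(t, k) = gdens(obs[t], mu[k], sigma[k]);

  // scaled forward pass
  double s = 0.0;
  for (int k = 0; k < K; ++k) { alpha(0, k) = pi0[k] * B(0, k); s += alpha(0, k); }
  if (s <= 0) s = 1e-300;
  c[0] = s;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s;
  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int j = 0; j < K; ++j) {
      double a = 0.0;
      for (int i = 0; i < K; ++i) a += alpha(t - 1, i) * A(i, j);
      a *= B(t, j);
      alpha(t, j) = a;
      s += a;
    }
    if (s <= 0) s = 1e-300;
    c[t] = s;
    for (int j = 0; j < K; ++j) alpha(t, j) /= s;
  }

  // scaled backward pass (Rabiner convention: beta_hat[T-1] = 1)
  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t)
    for (int i = 0; i < K; ++i) {
      double b = 0.0;
      for (int j = 0; j < K; ++j)
        b += A(i, j) * B(t + 1, j) * beta(t + 1, j);
      beta(t, i) = b / c[t + 1];
    }

  NumericVector S0(K), S1(K), S2(K), G1(K);
  NumericMatrix Xi(K, K);
  for (int t = 0; t < T; ++t) {
    double g = 0.0;
    for (int k = 0; k < K; ++k) g += alpha(t, k) * beta(t, k);
    if (g <= 0) g = 1e-300;
    for (int k = 0; k < K; ++k) {
      double gk = alpha(t, k) * beta(t, k) / g;
      S0[k] += gk;
      S1[k] += gk * obs[t];
      S2[k] += gk * obs[t] * obs[t];
      if (t == 0) G1[k] = gk;
    }
  }
  for (int t = 0; t < T - 1; ++t) {
    double z = 0.0;
    for (int i = 0; i < K; ++i)
      for (int j = 0; j < K; ++j)
        z += alpha(t, i) * A(i, j) * B(t + 1, j) * beta(t + 1, j);
    if (z <= 0) z = 1e-300;
    for (int i = 0; i < K; ++i)
      for (int j = 0; j < K; ++j)
        Xi(i, j) += alpha(t, i) * A(i, j) * B(t + 1, j) * beta(t + 1, j) / z;
  }

  double ll = 0.0;
  for (int t = 0; t < T; ++t) ll += std::log(c[t]);

  return List::create(_["loglik"] = ll, _["S0"] = S0, _["S1"] = S1,
                      _["S2"] = S2, _["Xi"] = Xi, _["G1"] = G1);
}

// Most-probable state sequence (1-based) and its log joint probability.
// [[Rcpp::export]]
List hmm_viterbi(NumericVector obs, NumericVector mu, NumericVector sigma,
                 NumericMatrix A, NumericVector pi0) {
  const int T = obs.size(), K = mu.size();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  NumericMatrix logA(K, K);
  const double NEG = -1e308;
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j)
      logA(i, j) = A(i, j) > 0 ? std::log(A(i, j)) : NEG;

  for (int k = 0; k < K; ++k)
    delta(0, k) = (pi0[k] > 0 ? std::log(pi0[k]) : NEG) +
                  std::log(gdens(obs[0], mu[k], sigma[k]));
  for (int t = 1; t < T; ++t)
    for (int j = 0; j < K; ++j) {
      double best = delta(t - 1, 0) + logA(0, j);
      int arg = 0;
      for (int i = 1; i < K; ++i) {
        double v = delta(t - 1, i) + logA(i, j);
        if (v > best) { best = v; arg = i; }
      }
      delta(t, j) = best + std::log(gdens(obs[t], mu[j], sigma[j]));
      psi(t, j) = arg;
    }

  IntegerVector path(T);
  int arg = 0;
  double best = delta(T - 1, 0);
  for (int k = 1; k < K; ++k)
    if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  path[T - 1] = arg;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  for (int t = 0; t < T; ++t) path[t] += 1;  // 1-based for R

  return List::create(_["path"] = path, _["logprob"] = best);
}
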