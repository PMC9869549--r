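#include <Rcpp.h>
using namespace Rcpp;

// Log-space forward/backward/Viterbi recursions for a K-state HMM with
// Gaussian emissions over a single observation sequence. Kept in C++ because
// the recursions are inherently sequential over tens of thousands of bins.

static inline double logsumexp(const std::vector<double>& v) {
  double m = v[0];
  for (size_t i = 1; i < v.size(); ++i) if (v[i] > m) m = v[i];
  if (!R_finite(m)) return m;
  double s = 0.0;
  for (size_t i = 0; i < v.size(); ++i) s += std::exp(v[i] - m);
  return m + std::log(s);
}

static NumericMatrix emission_logprob(const NumericVector& x,
                                      const NumericVector& mu,
                                      const NumericVector& sigma) {
  const int T = x.size(), K = mu.size();
  NumericMatrix lb(T, K);
  for (int k = 0; k < K; ++k) {
    const double s = sigma[k];
    const double c = -0.5 * std::log(2.0 * M_PI) - std::log(s);
    for (int t = 0; t < T; ++t) {
      const double z = (x[t] - mu[k]) / s;
      lb(t, k) = c - 0.5 * z * z;
    }
  }
  return lb;
}

// Forward log-likelihood of one sequence.
// [[Rcpp::export(name = ".hmm_forward_cpp")]]
double hmm_forward_cpp(NumericVector x, NumericVector logpi,
                       NumericMatrix logA, NumericVector mu,
                       NumericVector sigma) {
  const int T = x.size(), K = mu.size();
  NumericMatrix lb = emission_logprob(x, mu, sigma);
  std::vector<double> alpha(K), prev(K), acc(K);
  for (int k = 0; k < K; ++k) alpha[k] = logpi[k] + lb(0, k);
  for (int t = 1; t < T; ++t) {
    prev = alpha;
    for (int k = 0; k < K; ++k) {
      for (int j = 0; j < K; ++j) acc[j] = prev[j] + logA(j, k);
      alpha[k] = logsumexp(acc) + lb(t, k);
    }
  }
  return logsumexp(alpha);
}

// Full E-step for one sequence: log-likelihood, posterior state
// probabilities gamma (T x K) and expected transition counts (K x K).
// [[Rcpp::export(name = ".hmm_estep_cpp")]]
List hmm_estep_cpp(NumericVector x, NumericVector logpi, NumericMatrix logA,
                   NumericVector mu, NumericVector sigma) {
  const int T = x.size(), K = mu.size();
  NumericMatrix lb = emission_logprob(x, mu, sigma);
  NumericMatrix la(T, K), lbk(T, K);
  std::vector<double> acc(K);
  for (int k = 0; k < K; ++k) la(0, k) = logpi[k] + lb(0, k);
  for (int t = 1; t < T; ++t)
    for (int k = 0; k < K; ++k) {
      for (int j = 0; j < K; ++j) acc[j] = la(t - 1, j) + logA(j, k);
      la(t, k) = logsumexp(acc) + lb(t, k);
    }
  for (int k = 0; k < K; ++k) lbk(T - 1, k) = 0.0;
  for (int t = T - 2; t >= 0; --t)
    for (int k = 0; k < K; ++k) {
      for (int j = 0; j < K; ++j)
        acc[j] = logA(k, j) + lb(t + 1, j) + lbk(t + 1, j);
      lbk(t, k) = logsumexp(acc);
    }
  for (int k = 0; k < K; ++k) acc[k] = la(T - 1, k);
  const double loglik = logsumexp(acc);

  NumericMatrix gamma(T, K);
  for (int t = 0; t < T; ++t) {
    double m = R_NegInf;
    for (int k = 0; k < K; ++k) {
      gamma(t, k) = la(t, k) + lbk(t, k);
      if (gamma(t, k) > m) m = gamma(t, k);
    }
    double s = 0.0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = std::exp(gamma(t, k) - m); s += gamma(t, k); }
    for (int k = 0; k < K; ++k) gamma(t, k) /= s;
  }

  NumericMatrix xi(K, K);
  for (int t = 0; t < T - 1; ++t) {
    // xi_t(j,k) proportional to alpha_t(j) A(j,k) b_{t+1}(k) beta_{t+1}(k)
    double m = R_NegInf;
    std::vector<double> lx(K * K);
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k) {
        double v = la(t, j) + logA(j, k) + lb(t + 1, k) + lbk(t + 1, k);
        lx[j * K + k] = v;
        if (v > m) m = v;
      }
    double s = 0.0;
    for (int i = 0; i < K * K; ++i) s += std::exp(lx[i] - m);
    const double lz = m + std::log(s);
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k)
        xi(j, k) += std::exp(lx[j * K + k] - lz);
  }
  return List::create(_["loglik"] = loglik, _["gamma"] = gamma,
                      _["xi"] = xi);
}

// Most probable joint state path; ties resolved toward the lower state
// index (strict improvement required to switch).
// [[Rcpp::export(name = ".hmm_viterbi_cpp")]]
IntegerVector hmm_viterbi_cpp(NumericVector x, NumericVector logpi,
                              NumericMatrix logA, NumericVector mu,
                              NumericVector sigma) {
  const int T = x.size(), K = mu.size();
  NumericMatrix lb = emission_logprob(x, mu, sigma);
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  for (int k = 0; k < K; ++k) delta(0, k) = logpi[k] + lb(0, k);
  for (int t = 1; t < T; ++t)
    for (int k = 0; k < K; ++k) {
      int arg = 0;
      double best = delta(t - 1, 0) + logA(0, k);
      for (int j = 1; j < K; ++j) {
        const double v = delta(t - 1, j) + logA(j, k);
        if (v > best) { best = v; arg = j; }
      }
      delta(t, k) = best + lb(t, k);
      psi(t, k) = arg;
    }
  IntegerVector path(T);
  int arg = 0;
  double best = delta(T - 1, 0);
  for (int k = 1; k < K; ++k)
    if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  path[T - 1] = arg;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  return path;
}
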