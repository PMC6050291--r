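#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for one observation segment.
//
// logB: T x K matrix of per-frame log emission probabilities,
// A: K x K row-stochastic transition matrix, pi: initial distribution.
// Works in probability space after shifting each logB row by its max, the
// standard scaling trick; returns the exact log-likelihood plus the
// posterior state probabilities (gamma) and summed two-slice posteriors
// (xi_sum) needed by Baum-Welch.
// [[Rcpp::export]]
List hmm_forward_backward(NumericMatrix logB, NumericMatrix A,
                          NumericVector pi, bool want_posteriors) {
  const int T = logB.nrow(), K = logB.ncol();
  NumericMatrix b(T, K);
  NumericVector shift(T);
  for (int t = 0; t < T; ++t) {
    double m = logB(t, 0);
    for (int k = 1; k < K; ++k) if (logB(t, k) > m) m = logB(t, k);
    if (!R_finite(m)) m = 0.0; // all -Inf row: emission impossible everywhere
    shift[t] = m;
    for (int k = 0; k < K; ++k) b(t, k) = std::exp(logB(t, k) - m);
  }
  NumericMatrix alpha(T, K);
  NumericVector cvec(T);
  double ll = 0.0;
  for (int t = 0; t < T; ++t) {
    double s = 0.0;
    if (t == 0) {
      for (int k = 0; k < K; ++k) { alpha(0, k) = pi[k] * b(0, k); s += alpha(0, k); }
    } else {
      for (int j = 0; j < K; ++j) {
        double a = 0.0;
        for (int i = 0; i < K; ++i) a += alpha(t - 1, i) * A(i, j);
        alpha(t, j) = a * b(t, j);
        s += alpha(t, j);
      }
    }
    if (s <= 0.0) {
      return List::create(_["loglik"] = R_NegInf, _["degenerate"] = true);
    }
    cvec[t] = s;
    for (int k = 0; k < K; ++k) alpha(t, k) /= s;
    ll += std::log(s) + shift[t];
  }
  if (!want_posteriors) {
    return List::create(_["loglik"] = ll, _["degenerate"] = false);
  }
  NumericMatrix beta(T, K), gamma(T, K);
  NumericMatrix xi(K, K);
  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int i = 0; i < K; ++i) {
      double s = 0.0;
      for (int j = 0; j < K; ++j) s += A(i, j) * b(t + 1, j) * beta(t + 1, j);
      beta(t, i) = s / cvec[t + 1];
    }
  }
  for (int t = 0; t < T; ++t) {
    double s = 0.0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); s += gamma(t, k); }
    for (int k = 0; k < K; ++k) gamma(t, k) /= s;
  }
  for (int t = 0; t < T - 1; ++t) {
    for (int i = 0; i < K; ++i) {
      double ai = alpha(t, i);
      for (int j = 0; j < K; ++j)
        xi(i, j) += ai * A(i, j) * b(t + 1, j) * beta(t + 1, j) / cvec[t + 1];
    }
  }
  return List::create(_["loglik"] = ll, _["degenerate"] = false,
                      _["gamma"] = gamma, _["xi_sum"] = xi);
}

// Viterbi decoding in log space. Ties broken toward the lower state index
// (strict > required to replace the incumbent).
// [[Rcpp::export]]
IntegerVector hmm_viterbi_path(NumericMatrix logB, NumericMatrix A,
                               NumericVector pi) {
  const int T = logB.nrow(), K = logB.ncol();
  NumericMatrix logA(K, K);
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j)
      logA(i, j) = A(i, j) > 0 ? std::log(A(i, j)) : R_NegInf;
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  for (int k = 0; k < K; ++k)
    delta(0, k) = (pi[k] > 0 ? std::log(pi[k]) : R_NegInf) + logB(0, k);
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < K; ++j) {
      double best = delta(t - 1, 0) + logA(0, j);
      int arg = 0;
      for (int i = 1; i < K; ++i) {
        double v = delta(t - 1, i) + logA(i, j);
        if (v > best) { best = v; arg = i; }
      }
      delta(t, j) = best + logB(t, j);
      psi(t, j) = arg;
    }
  }
  IntegerVector path(T);
  int arg = 0;
  double best = delta(T - 1, 0);
  for (int k = 1; k < K; ++k) if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  path[T - 1] = arg;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  for (int t = 0; t < T; ++t) path[t] += 1; // 1-based state labels for R
  return path;
}
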