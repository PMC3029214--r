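#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Per-component log densities of a diagonal-covariance Gaussian
// mixture: returns T x M matrix of log(w_m) + log N(x_t; mu_m, var_m).
// [[Rcpp::export(name = ".gmm_comp_logdens_cpp")]]
NumericMatrix gmm_comp_logdens_cpp(NumericMatrix X, NumericMatrix mu,
                                   NumericMatrix var, NumericVector logw) {
  int T = X.nrow(), d = X.ncol(), M = mu.nrow();
  NumericMatrix out(T, M);
  std::vector<double> cst(M);
  for (int m = 0; m < M; ++m) {
    double c = -0.5 * d * std::log(2.0 * M_PI);
    for (int k = 0; k < d; ++k) c -= 0.5 * std::log(var(m, k));
    cst[m] = c + logw[m];
  }
  for (int t = 0; t < T; ++t)
    for (int m = 0; m < M; ++m) {
      double q = 0.0;
      for (int k = 0; k < d; ++k) {
        double diff = X(t, k) - mu(m, k);
        q += diff * diff / var(m, k);
      }
      out(t, m) = cst[m] - 0.5 * q;
    }
  return out;
}

// Scaled forward recursion. logB is T x S per-state log emission
// densities, A the S x S transition matrix, pi the initial distribution.
// Returns log P(observations | model).
// [[Rcpp::export(name = ".hmm_forward_cpp")]]
double hmm_forward_cpp(NumericMatrix logB, NumericMatrix A, NumericVector pi) {
  int T = logB.nrow(), S = logB.ncol();
  std::vector<double> alpha(S), anew(S);
  double loglik = 0.0;
  for (int t = 0; t < T; ++t) {
    double cmax = R_NegInf;
    for (int s = 0; s < S; ++s) cmax = std::max(cmax, logB(t, s));
    if (!R_finite(cmax)) cmax = 0.0;  // all emissions -Inf: handled below
    double tot = 0.0;
    for (int s = 0; s < S; ++s) {
      double prev;
      if (t == 0) prev = pi[s];
      else {
        prev = 0.0;
        for (int q = 0; q < S; ++q) prev += alpha[q] * A(q, s);
      }
      anew[s] = prev * std::exp(logB(t, s) - cmax);
      tot += anew[s];
    }
    if (tot <= 0.0 || !R_finite(tot)) return R_NegInf;
    for (int s = 0; s < S; ++s) alpha[s] = anew[s] / tot;
    loglik += std::log(tot) + cmax;
  }
  return loglik;
}

// Scaled forward-backward. Returns the sequence log-likelihood, the
// T x S state posteriors gamma, and the S x S expected transition
// counts summed over t (the Baum-Welch xi accumulator).
// [[Rcpp::export(name = ".hmm_fb_cpp")]]
List hmm_fb_cpp(NumericMatrix logB, NumericMatrix A, NumericVector pi) {
  int T = logB.nrow(), S = logB.ncol();
  NumericMatrix alpha(T, S), beta(T, S), b(T, S), gamma(T, S), xi(S, S);
  NumericVector scale(T), cmaxv(T);
  double loglik = 0.0;
  for (int t = 0; t < T; ++t) {
    double cmax = R_NegInf;
    for (int s = 0; s < S; ++s) cmax = std::max(cmax, logB(t, s));
    if (!R_finite(cmax)) cmax = 0.0;
    cmaxv[t] = cmax;
    for (int s = 0; s < S; ++s) b(t, s) = std::exp(logB(t, s) - cmax);
  }
  for (int t = 0; t < T; ++t) {
    double tot = 0.0;
    for (int s = 0; s < S; ++s) {
      double prev;
      if (t == 0) prev = pi[s];
      else {
        prev = 0.0;
        for (int q = 0; q < S; ++q) prev += alpha(t - 1, q) * A(q, s);
      }
      alpha(t, s) = prev * b(t, s);
      tot += alpha(t, s);
    }
    if (tot <= 0.0 || !R_finite(tot)) {
      return List::create(_["loglik"] = R_NegInf, _["underflow"] = true);
    }
    scale[t] = tot;
    for (int s = 0; s < S; ++s) alpha(t, s) /= tot;
    loglik += std::log(tot) + cmaxv[t];
  }
  for (int s = 0; s < S; ++s) beta(T - 1, s) = 1.0;
  for (int t = T - 2; t >= 0; --t)
    for (int s = 0; s < S; ++s) {
      double acc = 0.0;
      for (int q = 0; q < S; ++q)
        acc += A(s, q) * b(t + 1, q) * beta(t + 1, q);
      beta(t, s) = acc / scale[t + 1];
    }
  for (int t = 0; t < T; ++t) {
    double tot = 0.0;
    for (int s = 0; s < S; ++s) {
      gamma(t, s) = alpha(t, s) * beta(t, s);
      tot += gamma(t, s);
    }
    for (int s = 0; s < S; ++s) gamma(t, s) /= tot;
  }
  for (int t = 0; t < T - 1; ++t) {
    double tot = 0.0;
    NumericMatrix tmp(S, S);
    for (int s = 0; s < S; ++s)
      for (int q = 0; q < S; ++q) {
        tmp(s, q) = alpha(t, s) * A(s, q) * b(t + 1, q) * beta(t + 1, q);
        tot += tmp(s, q);
      }
    if (tot > 0.0)
      for (int s = 0; s < S; ++s)
        for (int q = 0; q < S; ++q) xi(s, q) += tmp(s, q) / tot;
  }
  return List::create(_["loglik"] = loglik, _["gamma"] = gamma,
                      _["xi"] = xi, _["underflow"] = false);
}
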