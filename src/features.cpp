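#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Approximate entropy with self-matches included (Pincus' original
// definition): ApEn = Phi_m(r) - Phi_{m+1}(r), Phi_m the mean over i of
// log of the fraction of templates within max-norm distance r.
// r is an absolute tolerance here; the R wrapper scales by SD(x).
// [[Rcpp::export(name = ".apen_cpp")]]
double apen_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  double phi[2];
  for (int pass = 0; pass < 2; ++pass) {
    int mm = m + pass;
    int nt = n - mm + 1;            // number of templates
    if (nt < 1) return NA_REAL;
    double acc = 0.0;
    for (int i = 0; i < nt; ++i) {
      int cnt = 0;
      for (int j = 0; j < nt; ++j) {
        bool ok = true;
        for (int k = 0; k < mm; ++k) {
          if (std::fabs(x[i + k] - x[j + k]) > r) { ok = false; break; }
        }
        if (ok) ++cnt;
      }
      acc += std::log((double)cnt / nt);   // cnt >= 1 (self-match)
    }
    phi[pass] = acc / nt;
  }
  return phi[0] - phi[1];
}

// Mean log divergence curve for the Rosenstein small-data Lyapunov
// method. emb is the N x m delay-embedded trajectory; for each point
// the nearest neighbour at temporal separation > theiler is found and
// the pair's distance is tracked for t = 0..maxt steps.
// Returns maxt+1 mean-log-distance values (NaN where no pair remains).
// [[Rcpp::export(name = ".lyap_divergence_cpp")]]
NumericVector lyap_divergence_cpp(NumericMatrix emb, int theiler, int maxt) {
  int n = emb.nrow(), m = emb.ncol();
  std::vector<int> nb(n, -1);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < n; ++j) {
      if (std::abs(i - j) <= theiler) continue;
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double diff = emb(i, k) - emb(j, k);
        d += diff * diff;
      }
      if (d < best && d > 0.0) { best = d; nb[i] = j; }
    }
  }
  NumericVector out(maxt + 1);
  for (int t = 0; t <= maxt; ++t) {
    double acc = 0.0; int cnt = 0;
    for (int i = 0; i < n; ++i) {
      int j = nb[i];
      if (j < 0 || i + t >= n || j + t >= n) continue;
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double diff = emb(i + t, k) - emb(j + t, k);
        d += diff * diff;
      }
      if (d > 0.0) { acc += 0.5 * std::log(d); ++cnt; }
    }
    out[t] = cnt > 0 ? acc / cnt : NA_REAL;
  }
  return out;
}

// Two-pole digital resonator with per-sample centre frequency and
// bandwidth (Klatt formulation, unity gain at DC). Used by the
// source-filter synthesizer for formant trajectories.
// [[Rcpp::export(name = ".resonator_tv_cpp")]]
NumericVector resonator_tv_cpp(NumericVector x, NumericVector f_hz,
                               NumericVector bw_hz, double fs) {
  int n = x.size();
  NumericVector y(n);
  double y1 = 0.0, y2 = 0.0;
  for (int i = 0; i < n; ++i) {
    double r = std::exp(-M_PI * bw_hz[i] / fs);
    double B = 2.0 * r * std::cos(2.0 * M_PI * f_hz[i] / fs);
    double C = -r * r;
    double A = 1.0 - B - C;
    double yi = A * x[i] + B * y1 + C * y2;
    y2 = y1; y1 = yi;
    y[i] = yi;
  }
  return y;
}
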