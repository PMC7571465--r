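#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Two-component normal-mixture EM at every scan position, with fixed
// per-individual priors (from flanking-marker genotypes). For each column j
// of P (prior probability that line i carries the aa QTL genotype) the
// mixture (mu1, mu2, common sigma^2) is fitted to y by EM and compared with
// the single-normal null on the same phenotype; returns per position the
// LOD, the additive effect (mu1 - mu2)/2, the prior-based genetic variance
// and the fitted parameters.
//
// [[Rcpp::export]]
NumericMatrix em_scan_cpp(NumericVector y, NumericMatrix P,
                          int maxit = 50, double tol = 1e-8) {
  const int n = y.size();
  const int k = P.ncol();
  if (P.nrow() != n) stop("P must have one row per phenotype value");
  NumericMatrix out(k, 6);
  colnames(out) = CharacterVector::create("lod", "additive", "gvar",
                                          "mu1", "mu2", "sigma2");

  // null model: single normal, ML fit
  double mean0 = 0.0;
  for (int i = 0; i < n; ++i) mean0 += y[i];
  mean0 /= n;
  double s0 = 0.0;
  for (int i = 0; i < n; ++i) s0 += (y[i] - mean0) * (y[i] - mean0);
  s0 /= n;
  const double sfloor = std::max(s0, 1e-300) * 1e-12 + 1e-300;
  const double ll0 = -0.5 * n * (std::log(2.0 * M_PI * std::max(s0, sfloor)) + 1.0);

  std::vector<double> post(n);
  for (int j = 0; j < k; ++j) {
    // init from prior-weighted class means
    double sw = 0.0, swy = 0.0, su = 0.0, suy = 0.0;
    for (int i = 0; i < n; ++i) {
      const double w = P(i, j);
      sw += w; swy += w * y[i];
      su += 1.0 - w; suy += (1.0 - w) * y[i];
    }
    double mu1 = sw > 1e-12 ? swy / sw : mean0;
    double mu2 = su > 1e-12 ? suy / su : mean0;
    double sig = std::max(s0, sfloor);
    double ll = -1e300, llold;
    for (int it = 0; it < maxit; ++it) {
      llold = ll;
      // E step
      ll = 0.0;
      const double inv2s = 0.5 / sig;
      const double lognorm = -0.5 * std::log(2.0 * M_PI * sig);
      for (int i = 0; i < n; ++i) {
        const double w = P(i, j);
        const double d1 = y[i] - mu1, d2 = y[i] - mu2;
        // scale by the larger exponent for stability
        const double e1 = -d1 * d1 * inv2s, e2 = -d2 * d2 * inv2s;
        const double m = e1 > e2 ? e1 : e2;
        const double f1 = w * std::exp(e1 - m);
        const double f2 = (1.0 - w) * std::exp(e2 - m);
        const double tot = f1 + f2;
        post[i] = tot > 0 ? f1 / tot : w;
        ll += lognorm + m + std::log(std::max(tot, 1e-300));
      }
      if (std::fabs(ll - llold) < tol * (std::fabs(llold) + 1.0)) break;
      // M step
      double p1 = 0.0, p1y = 0.0, p2 = 0.0, p2y = 0.0;
      for (int i = 0; i < n; ++i) {
        p1 += post[i]; p1y += post[i] * y[i];
        p2 += 1.0 - post[i]; p2y += (1.0 - post[i]) * y[i];
      }
      if (p1 > 1e-12) mu1 = p1y / p1;
      if (p2 > 1e-12) mu2 = p2y / p2;
      double ss = 0.0;
      for (int i = 0; i < n; ++i) {
        const double d1 = y[i] - mu1, d2 = y[i] - mu2;
        ss += post[i] * d1 * d1 + (1.0 - post[i]) * d2 * d2;
      }
      sig = std::max(ss / n, sfloor);
    }
    // prior-based genetic variance of the fitted QTL effect
    double eg = 0.0, eg2 = 0.0;
    for (int i = 0; i < n; ++i) {
      const double w = P(i, j);
      const double g = w * mu1 + (1.0 - w) * mu2;
      eg += g;
      eg2 += w * mu1 * mu1 + (1.0 - w) * mu2 * mu2;
    }
    eg /= n; eg2 /= n;
    out(j, 0) = std::max(0.0, (ll - ll0) / std::log(10.0));
    out(j, 1) = (mu1 - mu2) / 2.0;
    out(j, 2) = std::max(0.0, eg2 - eg * eg);
    out(j, 3) = mu1;
    out(j, 4) = mu2;
    out(j, 5) = sig;
  }
  return out;
}
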