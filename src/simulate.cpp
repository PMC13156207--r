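// Trial-level Euler-Maruyama simulators for the dynaViTE family and the
// Wiener race models.  The decision path is simulated step by step (absorbing
// boundaries) with a Brownian-bridge correction for within-step boundary
// crossings, which removes the O(sqrt(delta)) first-passage bias of the
// plain Euler scheme.  The post-decisional decision increment and the
// visibility evidence are drawn exactly from their Gaussian laws.  Uses R's
// RNG, so set.seed() governs reproducibility.

#include <Rcpp.h>
using namespace Rcpp;

// columns: response, t_dec, conf
// response 0 with NA fields when no boundary is hit before maxrt
// [[Rcpp::export]]
NumericMatrix cpp_sim_dynaViTE(int n, double a, double z, double sz,
                               double nu, double snu, double tau,
                               double muv, double sigvis, double svis,
                               double w, double lambda, double s,
                               double delta, double maxrt) {
  NumericMatrix out(n, 3);
  double sqdelta = std::sqrt(delta);
  bool use_vis = (w < 1.0);
  for (int i = 0; i < n; i++) {
    double v = (snu > 0.0) ? R::rnorm(nu, snu) : nu;
    double zr = (sz > 0.0) ? R::runif(z - sz / 2.0, z + sz / 2.0) : z;
    double mv = (use_vis && sigvis > 0.0) ? R::rnorm(muv, sigvis)
                                          : (use_vis ? muv : 0.0);
    double x = a * zr;
    double t = 0.0;
    int resp = 0;
    double sd2 = s * s * delta;
    while (t < maxrt) {
      double xprev = x;
      x += v * delta + s * sqdelta * R::norm_rand();
      t += delta;
      if (x >= a) { resp = 1; break; }
      if (x <= 0.0) { resp = -1; break; }
      // Brownian-bridge probability of an unseen within-step crossing
      double pup = std::exp(-2.0 * (a - xprev) * (a - x) / sd2);
      double plo = std::exp(-2.0 * xprev * x / sd2);
      double u = R::unif_rand();
      if (u < pup) { resp = 1; break; }
      if (u < pup + plo) { resp = -1; break; }
    }
    if (resp == 0) {
      out(i, 0) = 0; out(i, 1) = NA_REAL; out(i, 2) = NA_REAL;
      continue;
    }
    // clamp to the boundary, then draw the post-decisional increment exactly
    double xT = (resp == 1) ? a : 0.0;
    double xpost = xT + ((tau > 0.0) ? v * tau + s * std::sqrt(tau) * R::norm_rand() : 0.0);
    double evid = resp * (xpost - a * z);
    double vis = 0.0;
    if (use_vis) {
      double ttau = t + tau;
      vis = mv * ttau + svis * std::sqrt(ttau) * R::norm_rand();
    }
    double c = w * evid + (use_vis ? (1.0 - w) * vis : 0.0);
    if (lambda != 0.0) c /= std::pow(t + tau, lambda);
    out(i, 0) = resp; out(i, 1) = t; out(i, 2) = c;
  }
  return out;
}

// columns: response (1/2), t_dec, b (loser's gap), conf
// [[Rcpp::export]]
NumericMatrix cpp_sim_race(int n, double A, double B, double mu1, double mu2,
                           double s1, double s2, double rho,
                           double wX, double wRT, double wInt,
                           bool time_dependent, double delta, double maxrt) {
  NumericMatrix out(n, 4);
  double sqdelta = std::sqrt(delta);
  double rr = std::sqrt(1.0 - rho * rho);
  for (int i = 0; i < n; i++) {
    double x1 = 0.0, x2 = 0.0, t = 0.0;
    int resp = 0;
    double v1d = s1 * s1 * delta, v2d = s2 * s2 * delta;
    while (t < maxrt) {
      double x1p = x1, x2p = x2;
      double e1 = R::norm_rand();
      double e2 = rho * e1 + rr * R::norm_rand();
      x1 += mu1 * delta + s1 * sqdelta * e1;
      x2 += mu2 * delta + s2 * sqdelta * e2;
      t += delta;
      bool h1 = x1 >= A, h2 = x2 >= B;
      if (!h1 && !h2) {
        // marginal Brownian-bridge corrections for within-step crossings
        double p1 = std::exp(-2.0 * (A - x1p) * (A - x1) / v1d);
        double p2 = std::exp(-2.0 * (B - x2p) * (B - x2) / v2d);
        h1 = R::unif_rand() < p1;
        h2 = R::unif_rand() < p2;
      }
      if (h1 && h2) { resp = (R::unif_rand() < 0.5) ? 1 : 2; break; }
      if (h1) { resp = 1; break; }
      if (h2) { resp = 2; break; }
    }
    if (resp == 0) {
      out(i, 0) = 0; out(i, 1) = NA_REAL; out(i, 2) = NA_REAL;
      out(i, 3) = NA_REAL;
      continue;
    }
    double b = (resp == 1) ? B - x2 : A - x1;
    if (b < 0.0) b = 0.0;
    double c = time_dependent
      ? wX * b + wRT / std::sqrt(t) + wInt * b / std::sqrt(t)
      : b;
    out(i, 0) = resp; out(i, 1) = t; out(i, 2) = b; out(i, 3) = c;
  }
  return out;
}
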