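// Joint density of (RT, response, confidence in [th1, th2]) for the
// dynaViTE family of drift-diffusion confidence models.
//
// First-passage time densities use the truncated small-time / large-time
// series with the minimal-terms switching criterion (Navarro & Fuss, 2009).
// Across-trial drift variability is handled analytically: the drift enters
// the FPT density only through exp(linear - quadratic) terms, so a normal
// drift marginalizes in closed form and the drift posterior given the
// first-passage event is Gaussian.  Starting-point and non-decision-time
// variability are integrated by the midpoint (rectangular) rule with
// equidistant support points; step counts are controlled by `precision`.

#include <Rcpp.h>
using namespace Rcpp;

// number of midpoint support points for a numeric integration over `range`;
// calibrated so that the mean absolute density error is about 10^-precision
// (see the precision benchmark); constants frozen by regression tests.
static int n_midpoints(double range, double precision, double cal, int cap) {
  if (range <= 0.0) return 1;
  double n = std::ceil(cal * range * std::pow(10.0, precision / 2.0));
  if (n < 4.0) n = 4.0;
  if (n > (double)cap) n = (double)cap;
  return (int)n;
}

// density (a = 1, drift = 0, diffusion = 1) of the first passage through the
// LOWER boundary at scaled time tt, relative start w; absolute error <= eps.
static double f0_fpt(double tt, double w, double eps) {
  if (tt <= 0.0) return 0.0;
  // minimal number of terms for each representation
  double ks, kl;
  if (2.0 * std::sqrt(2.0 * M_PI * tt) * eps < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * tt * std::log(2.0 * eps * std::sqrt(2.0 * M_PI * tt)));
    ks = std::max(ks, std::sqrt(tt) + 1.0);
  } else {
    ks = 2.0;
  }
  if (M_PI * tt * eps < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * tt * eps) / (M_PI * M_PI * tt));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(tt)));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(tt));
  }
  double f = 0.0;
  if (ks < kl) { // small-time expansion
    int K = (int)std::ceil(ks);
    for (int k = -(K - 1) / 2; k <= K / 2; k++) {
      double x = w + 2.0 * k;
      f += x * std::exp(-x * x / (2.0 * tt));
    }
    f /= std::sqrt(2.0 * M_PI * tt * tt * tt);
  } else {       // large-time expansion
    int K = (int)std::ceil(kl);
    for (int k = 1; k <= K; k++) {
      f += k * std::exp(-k * k * M_PI * M_PI * tt / 2.0) *
        std::sin(k * M_PI * w);
    }
    f *= M_PI;
  }
  return f > 0.0 ? f : 0.0;
}

// closed-form factor from marginalizing drift ~ N(nu, eta^2) over
// exp(-nu*c1 - nu^2*c2/2); equals exp(-nu*c1 - nu^2*c2/2) when eta = 0.
static double drift_marginal(double nu, double eta, double c1, double c2) {
  double v = 1.0 + eta * eta * c2;
  return std::exp((c1 * c1 * eta * eta - 2.0 * nu * c1 - nu * nu * c2) /
                  (2.0 * v)) / std::sqrt(v);
}

// defective FPT density at boundary `response` (+1 upper / -1 lower) for
// decision time t, marginal over drift N(nu, snu^2), fixed relative start w.
static double fpt_ddm_one(double t, int response, double a, double w,
                          double nu, double snu, double s, double eps) {
  if (t <= 0.0) return 0.0;
  double ww = w, vnu = nu;
  if (response > 0) { ww = 1.0 - w; vnu = -nu; }
  double as = a / s;
  double tt = t / (as * as);
  double c1 = a * ww / (s * s);
  double c2 = t / (s * s);
  return drift_marginal(vnu, snu, c1, c2) * f0_fpt(tt, ww, eps) / (as * as);
}

// [[Rcpp::export]]
NumericVector cpp_fpt_ddm(NumericVector t, int response, double a, double z,
                          double sz, double nu, double snu, double s,
                          double precision) {
  int n = t.size();
  NumericVector out(n);
  double eps = std::pow(10.0, -(precision + 1.5));
  int nz = n_midpoints(sz, precision, 0.79, 250);
  for (int i = 0; i < n; i++) {
    double acc = 0.0;
    for (int j = 0; j < nz; j++) {
      double w = (sz > 0.0) ? z - sz / 2.0 + (j + 0.5) * sz / nz : z;
      acc += fpt_ddm_one(t[i], response, a, w, nu, snu, s, eps);
    }
    out[i] = acc / nz;
  }
  return out;
}

static inline double Phi(double x) { return 0.5 * std::erfc(-x * M_SQRT1_2); }

// P(th1 < c <= th2) of a Gaussian confidence variable with mean m, sd sd,
// where the interval is given on the raw c scale and scaled by `scale`.
static double conf_prob(double th1, double th2, double scale,
                        double m, double sd) {
  double lo = (R_finite(th1)) ? th1 * scale : R_NegInf;
  double hi = (R_finite(th2)) ? th2 * scale : R_PosInf;
  if (sd > 1e-12) {
    double p1 = R_finite(lo) ? Phi((lo - m) / sd) : 0.0;
    double p2 = R_finite(hi) ? Phi((hi - m) / sd) : 1.0;
    double p = p2 - p1;
    return p > 0.0 ? p : 0.0;
  }
  // degenerate confidence variable (e.g. DDConf): point mass at m
  return (m > lo && m <= hi) ? 1.0 : 0.0;
}

// [[Rcpp::export]]
NumericVector cpp_ddm_conf(NumericVector rt, IntegerVector response,
                           NumericVector th1, NumericVector th2,
                           NumericVector nu, NumericVector muv,
                           double a, double z, double sz, double snu,
                           double tau, double w, double lambda,
                           double svis, double sigvis,
                           double t0, double st0, double s,
                           double precision, bool simult_conf) {
  int n = rt.size();
  NumericVector out(n);
  double eps = std::pow(10.0, -(precision + 1.5));
  int nz = n_midpoints(sz, precision, 0.79, 250);
  int nt = n_midpoints(st0, precision, 0.79, 250);
  double s2 = s * s;
  // visibility contribution is skipped entirely when w == 1
  bool use_vis = (w < 1.0);
  for (int i = 0; i < n; i++) {
    double tbase = rt[i] - t0 - (simult_conf ? tau : 0.0);
    int R = response[i];
    double zeta_z = (R > 0) ? 1.0 - z : z;
    double acc = 0.0;
    for (int jt = 0; jt < nt; jt++) {
      double t = (st0 > 0.0) ? tbase - (jt + 0.5) * st0 / nt : tbase;
      if (t <= 0.0) continue;
      double ttau = t + tau;
      double scale = (lambda != 0.0) ? std::pow(ttau, lambda) : 1.0;
      // visibility evidence V(t+tau): N(muv*(t+tau), sigvis^2*(t+tau)^2 + svis^2*(t+tau))
      double mv = 0.0, varv = 0.0;
      if (use_vis) {
        mv = muv[i] * ttau;
        varv = sigvis * sigvis * ttau * ttau + svis * svis * ttau;
      }
      for (int jz = 0; jz < nz; jz++) {
        double zr = (sz > 0.0) ? z - sz / 2.0 + (jz + 0.5) * sz / nz : z;
        double fpt = fpt_ddm_one(t, R, a, zr, nu[i], snu, s, eps);
        if (fpt <= 0.0) continue;
        // Gaussian drift posterior given first passage at (t, R, zr)
        double zeta_r = (R > 0) ? 1.0 - zr : zr;
        double nu_t, var_t;
        if (snu > 0.0) {
          double prec = 1.0 / (snu * snu) + t / s2;
          nu_t = (nu[i] / (snu * snu) + R * a * zeta_r / s2) / prec;
          var_t = 1.0 / prec;
        } else {
          nu_t = nu[i];
          var_t = 0.0;
        }
        // decision evidence R*(X(t+tau) - a*z) | t, R: Gaussian
        double md = a * zeta_z + R * nu_t * tau;
        double vard = tau * tau * var_t + s2 * tau;
        double m = w * md + (use_vis ? (1.0 - w) * mv : 0.0);
        double var = w * w * vard + (use_vis ? (1.0 - w) * (1.0 - w) * varv : 0.0);
        acc += fpt * conf_prob(th1[i], th2[i], scale, m, std::sqrt(var));
      }
    }
    out[i] = acc / ((double)nz * (double)nt);
  }
  return out;
}
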