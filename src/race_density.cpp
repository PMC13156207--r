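// Joint density for two-accumulator Wiener race models with correlation
// rho in {0, -0.5}: first-passage time of the winning accumulator jointly
// with the losing accumulator's distance b to its own threshold
// (balance of evidence).
//
// Solved by the method of images.  In threshold-distance coordinates
// y = (K1 - X1, K2 - X2) the process starts at (K1, K2), has drift
// (-mu1, -mu2), unit variances and correlation rho, and is absorbed at
// y1 = 0 or y2 = 0.  For rho = 0 the wedge angle is pi/2 (4 images), for
// rho = -0.5 it is pi/3 (6 images, dihedral reflection group).  Drift is
// absorbed into constant image weights exp(c'(y_j - y0)) with
// c = Sigma^{-1} m.  The flux through the winner's boundary at loser
// position b integrates analytically over b-intervals, so confidence-bin
// probabilities need no numeric integration beyond the non-decision time.

#include <Rcpp.h>
using namespace Rcpp;

static inline double Phi(double x) { return 0.5 * std::erfc(-x * M_SQRT1_2); }
static inline double phi(double x) { return std::exp(-0.5 * x * x) * 0.3989422804014327; }

struct RaceImages {
  int n;
  double y1[6], y2[6]; // image points (winner coord first)
  double sgn[6];       // parity
  double lw[6];        // log Girsanov weight c'(y_j - y0)
};

// images of the start point (a, b0) for the wedge y1>0, y2>0 with
// correlation rho; drift m = (-mu_w, -mu_l)
static RaceImages race_images(double a, double b0, double mu_w, double mu_l,
                              double rho) {
  RaceImages im;
  // c = Sigma^{-1} m, Sigma = [[1, rho], [rho, 1]]
  double det = 1.0 - rho * rho;
  double c1 = (-mu_w + rho * mu_l) / det;
  double c2 = (rho * mu_w - mu_l) / det;
  if (rho == 0.0) {
    im.n = 4;
    double p1[4] = { a, -a,  a, -a };
    double p2[4] = { b0,  b0, -b0, -b0 };
    double sg[4] = { 1.0, -1.0, -1.0, 1.0 };
    for (int j = 0; j < 4; j++) {
      im.y1[j] = p1[j]; im.y2[j] = p2[j]; im.sgn[j] = sg[j];
    }
  } else { // rho = -0.5: map to isotropic coordinates, reflect in D3
    // y = T u with T = [[1, 0], [-1/2, sqrt(3)/2]]
    double s3 = std::sqrt(3.0);
    double u01 = a;
    double u02 = (b0 + 0.5 * a) * 2.0 / s3;
    // reflections: r1 about the u2-axis (boundary y1=0),
    // r2 about the 30-degree line (boundary y2=0)
    double u[6][2]; double sg[6];
    auto r1 = [](double* v) { v[0] = -v[0]; };
    auto r2 = [&s3](double* v) {
      double a1 = 0.5 * v[0] + (s3 / 2.0) * v[1];
      double a2 = (s3 / 2.0) * v[0] - 0.5 * v[1];
      v[0] = a1; v[1] = a2;
    };
    u[0][0] = u01; u[0][1] = u02; sg[0] = 1.0;            // e
    u[1][0] = u01; u[1][1] = u02; r1(u[1]); sg[1] = -1.0; // r1
    u[2][0] = u01; u[2][1] = u02; r2(u[2]); sg[2] = -1.0; // r2
    u[3][0] = u[1][0]; u[3][1] = u[1][1]; r2(u[3]); sg[3] = 1.0; // r2 r1
    u[4][0] = u[2][0]; u[4][1] = u[2][1]; r1(u[4]); sg[4] = 1.0; // r1 r2
    u[5][0] = u[3][0]; u[5][1] = u[3][1]; r1(u[5]); sg[5] = -1.0; // r1 r2 r1
    im.n = 6;
    for (int j = 0; j < 6; j++) {
      im.y1[j] = u[j][0];
      im.y2[j] = -0.5 * u[j][0] + (s3 / 2.0) * u[j][1];
      im.sgn[j] = sg[j];
    }
  }
  for (int j = 0; j < im.n; j++)
    im.lw[j] = c1 * (im.y1[j] - a) + c2 * (im.y2[j] - b0);
  return im;
}

// probability flux through the winner's boundary at decision time t with the
// loser's gap in [b1, b2]; set b1 = b2 = b and density = true for the joint
// density at gap b.  Thresholds/drifts already in the winner-first order.
static double race_fpt_mass(double t, double a, double b0, double mu_w,
                            double mu_l, double rho, double b1, double b2,
                            bool density, double b) {
  if (t <= 0.0) return 0.0;
  double det = 1.0 - rho * rho;
  double sig_c = std::sqrt(t * det);
  double sqt = std::sqrt(t);
  RaceImages im = race_images(a, b0, mu_w, mu_l, rho);
  double total = 0.0;
  for (int j = 0; j < im.n; j++) {
    double c1 = im.y1[j] - mu_w * t; // mean of Y1 at time t
    double c2 = im.y2[j] - mu_l * t;
    double m2 = c2 - rho * c1;       // E[Y2 | Y1 = 0]
    double g1 = phi(c1 / sqt) / sqt; // marginal density of Y1 at 0
    double wgt = im.sgn[j] * std::exp(im.lw[j]) * g1 / (2.0 * t * det);
    if (density) {
      double fb = phi((b - m2) / sig_c) / sig_c;
      total += wgt * (c1 + rho * (b - c2)) * fb;
    } else {
      double alpha = c1 - rho * c2;
      double z1 = R_finite(b1) ? (b1 - m2) / sig_c : R_NegInf;
      double z2 = R_finite(b2) ? (b2 - m2) / sig_c : R_PosInf;
      double P1 = R_finite(b1) ? Phi(z1) : 0.0;
      double P2 = R_finite(b2) ? Phi(z2) : 1.0;
      double f1 = R_finite(b1) ? phi(z1) : 0.0;
      double f2 = R_finite(b2) ? phi(z2) : 0.0;
      double I = alpha * (P2 - P1) + rho * (m2 * (P2 - P1) - sig_c * (f2 - f1));
      total += wgt * I;
    }
  }
  return total > 0.0 ? total : 0.0;
}

// [[Rcpp::export]]
NumericVector cpp_fpt_race(NumericVector t, IntegerVector winner,
                           NumericVector b, double A, double B,
                           double mu1, double mu2, double s1, double s2,
                           double rho) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; i++) {
    double v;
    if (winner[i] == 1) {
      v = race_fpt_mass(t[i], A / s1, B / s2, mu1 / s1, mu2 / s2, rho,
                        0, 0, true, b[i] / s2) / s2;
    } else {
      v = race_fpt_mass(t[i], B / s2, A / s1, mu2 / s2, mu1 / s1, rho,
                        0, 0, true, b[i] / s1) / s1;
    }
    out[i] = v;
  }
  return out;
}

static int n_midpoints_race(double range, double precision, double cal,
                            int cap) {
  if (range <= 0.0) return 1;
  double n = std::ceil(cal * range * std::pow(10.0, precision / 2.0));
  if (n < 4.0) n = 4.0;
  if (n > (double)cap) n = (double)cap;
  return (int)n;
}

// [[Rcpp::export]]
NumericVector cpp_race_conf(NumericVector rt, IntegerVector response,
                            NumericVector th1, NumericVector th2,
                            NumericVector mu1, NumericVector mu2,
                            double A, double B, double s1, double s2,
                            double rho, double wX, double wRT, double wInt,
                            double t0, double st0, bool time_dependent,
                            double precision) {
  int n = rt.size();
  NumericVector out(n);
  int nt = n_midpoints_race(st0, precision, 0.55, 2000);
  for (int i = 0; i < n; i++) {
    double tbase = rt[i] - t0;
    int R = response[i]; // 1 or 2
    double s_l = (R == 1) ? s2 : s1;
    double acc = 0.0;
    for (int jt = 0; jt < nt; jt++) {
      double t = (st0 > 0.0) ? tbase - (jt + 0.5) * st0 / nt : tbase;
      if (t <= 0.0) continue;
      // map the confidence interval [th1, th2] to a gap interval [b1, b2]
      double b1, b2;
      bool all_mass = false, no_mass = false;
      double lo = R_finite(th1[i]) ? th1[i] : R_NegInf;
      double hi = R_finite(th2[i]) ? th2[i] : R_PosInf;
      if (!time_dependent) { // c = b
        b1 = lo; b2 = hi;
      } else {
        double rtt = wRT / std::sqrt(t);
        double denom = wX + wInt / std::sqrt(t);
        if (denom > 0.0) {
          b1 = R_finite(lo) ? (lo - rtt) / denom : R_NegInf;
          b2 = R_finite(hi) ? (hi - rtt) / denom : R_PosInf;
        } else { // c depends on t only: indicator times the full gap mass
          if (rtt > lo && rtt <= hi) all_mass = true; else no_mass = true;
          b1 = R_NegInf; b2 = R_PosInf;
        }
      }
      if (no_mass) continue;
      if (!all_mass) {
        if (R_finite(b2) && b2 <= 0.0) continue;
        if (!R_finite(b1) || b1 < 0.0) b1 = 0.0;
        if (R_finite(b1) && R_finite(b2) && b1 >= b2) continue;
      } else {
        b1 = 0.0; b2 = R_PosInf;
      }
      double v;
      if (R == 1) {
        v = race_fpt_mass(t, A / s1, B / s2, mu1[i] / s1, mu2[i] / s2, rho,
                          b1 / s_l, R_finite(b2) ? b2 / s_l : R_PosInf,
                          false, 0.0);
      } else {
        v = race_fpt_mass(t, B / s2, A / s1, mu2[i] / s2, mu1[i] / s1, rho,
                          b1 / s_l, R_finite(b2) ? b2 / s_l : R_PosInf,
                          false, 0.0);
      }
      acc += v;
    }
    out[i] = acc / (double)nt;
  }
  return out;
}
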