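// Joint density for the multiple-threshold log-normal race model (MTLNR).
//
// Boundary crossing times are T_i = D_i / V_i with log-normal boundary
// distances D and rates V, so (log T_1, log T_2) is bivariate normal with
// mean (mu_d1 - mu_v1, mu_d2 - mu_v2) and covariance Sigma_d + Sigma_v
// (D and V independent; cov(-log V1, -log V2) = +rho_v*s_v1*s_v2).
// Confidence is log(T_lose / T_win) >= 0.  Only the uniform non-decision
// time needs numeric integration; the step count at equal precision is
// larger than for the Wiener race models (the log-time density is much
// more curved in t).

#include <Rcpp.h>
using namespace Rcpp;

static inline double Phi(double x) { return 0.5 * std::erfc(-x * M_SQRT1_2); }
static inline double phi(double x) { return std::exp(-0.5 * x * x) * 0.3989422804014327; }

static int n_midpoints_mtlnr(double range, double precision) {
  if (range <= 0.0) return 1;
  double n = std::ceil(1.6 * range * std::pow(10.0, precision / 2.0));
  if (n < 4.0) n = 4.0;
  if (n > 4000.0) n = 4000.0;
  return (int)n;
}

// [[Rcpp::export]]
NumericVector cpp_mtlnr_conf(NumericVector rt, IntegerVector response,
                             NumericVector th1, NumericVector th2,
                             NumericVector mu_v1, NumericVector mu_v2,
                             double mu_d1, double mu_d2,
                             double sigma_d1, double sigma_d2, double rho_d,
                             double sigma_v1, double sigma_v2, double rho_v,
                             double t0, double st0, double precision) {
  int n = rt.size();
  NumericVector out(n);
  double v1 = sigma_d1 * sigma_d1 + sigma_v1 * sigma_v1;
  double v2 = sigma_d2 * sigma_d2 + sigma_v2 * sigma_v2;
  double c12 = rho_d * sigma_d1 * sigma_d2 + rho_v * sigma_v1 * sigma_v2;
  int nt = n_midpoints_mtlnr(st0, precision);
  for (int i = 0; i < n; i++) {
    int R = response[i]; // 1 or 2 (winner)
    double m_w, m_l, v_w, v_l;
    if (R == 1) {
      m_w = mu_d1 - mu_v1[i]; m_l = mu_d2 - mu_v2[i];
      v_w = v1; v_l = v2;
    } else {
      m_w = mu_d2 - mu_v2[i]; m_l = mu_d1 - mu_v1[i];
      v_w = v2; v_l = v1;
    }
    double s_w = std::sqrt(v_w);
    double cvar = v_l - c12 * c12 / v_w;   // conditional var of loser's log time
    double csd = cvar > 0.0 ? std::sqrt(cvar) : 0.0;
    double lo = R_finite(th1[i]) ? th1[i] : 0.0;
    if (lo < 0.0) lo = 0.0;
    double tbase = rt[i] - t0;
    double acc = 0.0;
    for (int jt = 0; jt < nt; jt++) {
      double t = (st0 > 0.0) ? tbase - (jt + 0.5) * st0 / nt : tbase;
      if (t <= 0.0) continue;
      double y = std::log(t);
      double fw = phi((y - m_w) / s_w) / (s_w * t); // winner's log-normal density
      double cm = m_l + c12 / v_w * (y - m_w);      // loser's conditional mean
      double p;
      double yl = y + lo;
      double yh = R_finite(th2[i]) ? y + th2[i] : R_PosInf;
      if (csd > 1e-12) {
        double p1 = Phi((yl - cm) / csd);
        double p2 = R_finite(yh) ? Phi((yh - cm) / csd) : 1.0;
        p = p2 - p1;
      } else {
        p = (cm > yl && (!R_finite(yh) || cm <= yh)) ? 1.0 : 0.0;
      }
      if (p > 0.0) acc += fw * p;
    }
    out[i] = acc / (double)nt;
  }
  return out;
}
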