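// Hot-path evaluation of the box-scheme residual for the coupled
// membrane / particle system with the built-in stress model
// (bond springs + short-range repulsion + Kelvin-Voigt foundation).
// Mirrors the reference R implementation in R/newton.R; a regression
// test asserts the two agree to machine precision.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double L_FLOOR = 1e-4;
static const double R_GUARD = 1e-9;

// Screened contact repulsion; below the gap floor the law continues
// linearly with the slope at the floor (smooth, non-singular, keeps a
// strong restoring gradient for interpenetrating Newton iterates).
static inline double rep_stress(double l, double gamma, double tau) {
  const double lc = (l < L_FLOOR) ? L_FLOOR : l;
  const double e = std::exp(-lc / tau);
  double f = (gamma / lc) * (1.0 / lc + 1.0 / tau) * e;
  if (l < L_FLOOR) {
    const double fp = gamma * e *
      (-2.0 / (lc * lc * lc) - 1.0 / (lc * lc * tau) -
       (1.0 / (lc * lc) + 1.0 / (lc * tau)) / tau);
    f += fp * (l - L_FLOOR);
  }
  return f;
}

// [[Rcpp::export]]
NumericVector npw_residual_cpp(NumericVector x, int n, NumericVector ds,
                               NumericVector wq, NumericVector xi_b,
                               NumericVector Z_prev, double dt, List np,
                               bool joint, double Z0_fixed,
                               double ptc_eps, NumericVector th_prev) {
  const double lambda = np["lambda"], tau = np["tau"], bend = np["bend"],
               Efound = np["Efound"], T0 = np["T0"], gamma = np["gamma"],
               CK = np["CK"], nu = np["nu"], Fv = np["Fv"];
  const int nv = 6, m = nv * n + (joint ? 1 : 0);
  const double Z0 = joint ? x[nv * n] : Z0_fixed;
  NumericVector res(m);

  // node accessors (x interleaved theta,p,q,T,R,Z)
  auto TH = [&](int i) { return x[nv * i]; };
  auto P  = [&](int i) { return x[nv * i + 1]; };
  auto Q  = [&](int i) { return x[nv * i + 2]; };
  auto TT = [&](int i) { return x[nv * i + 3]; };
  auto RR = [&](int i) { return x[nv * i + 4]; };
  auto ZZ = [&](int i) { return x[nv * i + 5]; };

  // axis rows
  res[0] = TH(0);
  res[1] = Q(0);
  res[2] = RR(0);

  for (int i = 0; i < n - 1; ++i) {
    const double h = ds[i];
    const double thm = 0.5 * (TH(i) + TH(i + 1));
    const double pm  = 0.5 * (P(i) + P(i + 1));
    const double qm  = 0.5 * (Q(i) + Q(i + 1));
    const double Tm  = 0.5 * (TT(i) + TT(i + 1));
    const double Rm  = 0.5 * (RR(i) + RR(i + 1));
    const double Zm  = 0.5 * (ZZ(i) + ZZ(i + 1));
    const double xim = 0.5 * (xi_b[i] + xi_b[i + 1]);
    const double Zpm = 0.5 * (Z_prev[i] + Z_prev[i + 1]);

    const double dv = Z0 - Zm;
    double rr = std::sqrt(Rm * Rm + dv * dv);
    if (rr < R_GUARD) rr = R_GUARD;
    const double l = rr - 1.0;
    const double sina = Rm / rr, cosa = dv / rr;
    const double rep = rep_stress(l, gamma, tau);
    const double net = CK * xim * (l - lambda) - rep;
    const double sn = std::sin(thm), cs = std::cos(thm);
    const double s2 = sn * sn, c2 = cs * cs;
    const double r = (Rm > R_GUARD) ? Rm : R_GUARD;
    const double sigr = -net * sina;
    const double sigv = -Efound * (Zm + (Zm - Zpm) / dt) * cs + net * cosa;

    const double A0 = -Tm * sn * pm - Tm * s2 / r +
      bend * (2.0 * sn * cs / r * qm + cs * pm * qm +
              (c2 - s2) / r * pm * pm +
              sn * (s2 - 2.0 * c2) / (r * r) * pm +
              s2 * c2 / (r * r * r)) + sigr;
    const double B0 = Tm * cs * pm + Tm * sn * cs / r +
      bend * (-2.0 * c2 / r * qm + sn * pm * qm +
              2.0 * sn * cs / r * pm * pm +
              cs * (c2 - 2.0 * s2) / (r * r) * pm -
              sn * c2 * cs / (r * r * r)) + sigv;
    const double fT = -(cs * A0 + sn * B0);
    const double fq = (cs * B0 - sn * A0) / bend;

    const int base = nv * i + 3;
    res[base]     = (TH(i + 1) - TH(i)) / h - pm;
    res[base + 1] = (P(i + 1) - P(i)) / h - qm;
    res[base + 2] = (Q(i + 1) - Q(i)) / h - fq;
    if (ptc_eps > 0) {
      // pseudo-transient rotational dashpot (solver continuation aid;
      // accepted solutions always have ptc_eps = 0)
      const double thpm = 0.5 * (th_prev[i] + th_prev[i + 1]);
      res[base + 2] += ptc_eps * (thm - thpm) / dt / bend;
    }
    res[base + 3] = (TT(i + 1) - TT(i)) / h - fT;
    res[base + 4] = (RR(i + 1) - RR(i)) / h - cs;
    res[base + 5] = (ZZ(i + 1) - ZZ(i)) / h - sn;
  }

  // edge rows
  {
    const int i = n - 1;
    double rn = RR(i);
    if (rn < R_GUARD) rn = R_GUARD;
    const double snn = std::sin(TH(i)), csn = std::cos(TH(i));
    res[nv * n - 3] = ZZ(i);
    res[nv * n - 2] = P(i) + nu * snn / rn;
    const double Vn = -bend * (Q(i) + csn * P(i) / rn -
                               snn * csn / (rn * rn));
    res[nv * n - 1] = TT(i) * csn - Vn * snn - T0;
  }

  if (joint) {
    double acc = 0.0;
    for (int i = 0; i < n; ++i) {
      const double dv = Z0 - ZZ(i);
      double rr = std::sqrt(RR(i) * RR(i) + dv * dv);
      if (rr < R_GUARD) rr = R_GUARD;
      const double l = rr - 1.0;
      const double cosa = dv / rr;
      const double rep = rep_stress(l, gamma, tau);
      const double net = CK * xi_b[i] * (l - lambda) - rep;
      acc += wq[i] * net * cosa * 2.0 * M_PI * RR(i) * std::cos(TH(i));
    }
    res[nv * n] = Fv - acc;
  }
  return res;
}
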