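// Per-sample closed-loop simulation of the post-onset flight phase.
//
// The R side discretizes every transfer function (Tustin at Ts) and passes
// the digital coefficients here; this loop only iterates direct-form-II
// transposed filters and the planar kinematics.  Keeping the loop in C++
// makes grid estimation over thousands of candidate gain pairs cheap.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Filt {
  std::vector<double> b, a, s;  // a[0] normalized to 1; s = n states
  Filt(const NumericVector &bb, const NumericVector &aa) {
    int n = std::max(bb.size(), aa.size());
    b.assign(n, 0.0);
    a.assign(n, 0.0);
    for (int i = 0; i < bb.size(); ++i) b[i] = bb[i];
    for (int i = 0; i < aa.size(); ++i) a[i] = aa[i];
    double a0 = a[0];
    for (int i = 0; i < n; ++i) { b[i] /= a0; a[i] /= a0; }
    s.assign(n - 1, 0.0);
  }
  double step(double u) {
    int n = (int)s.size();
    double y = b[0] * u + (n > 0 ? s[0] : 0.0);
    for (int i = 0; i < n; ++i) {
      double nxt = (i + 1 < n) ? s[i + 1] : 0.0;
      s[i] = b[i + 1] * u - a[i + 1] * y + nxt;
    }
    return y;
  }
};

}  // namespace

// [[Rcpp::export]]
List sim_fall_post_cpp(double Ts, double g, double d_wall, double setpoint,
                       double x0, double z0, double vx0, double vz0,
                       double th0, double thd0,
                       NumericVector f_base,
                       NumericVector pd_b, NumericVector pd_a,
                       NumericVector hal_b, NumericVector hal_a,
                       bool improved,
                       NumericVector pdth_b, NumericVector pdth_a,
                       NumericVector piwz_b, NumericVector piwz_a,
                       double guard_theta, double guard_speed,
                       bool stop_at_floor, double zi_decay) {
  int n = f_base.size();
  Filt pd(pd_b, pd_a), hal(hal_b, hal_a);
  Filt pdth(pdth_b, pdth_a), piwz(piwz_b, piwz_a);
  // the passive pitch rate at onset decays through the wing-pitch actuator
  // lag while the closed-loop command takes over
  double zi = thd0;

  NumericVector X(n, NA_REAL), Z(n, NA_REAL), VX(n, NA_REAL), VZ(n, NA_REAL),
      TH(n, NA_REAL), THD(n, NA_REAL), F(n, NA_REAL), Lv(n, NA_REAL),
      Tv(n, NA_REAL), WX(n, NA_REAL), WZ(n, NA_REAL);

  double x = x0, z = z0, vx = vx0, vz = vz0, th = th0, thd = thd0;
  bool diverged = false, crashed = false;
  int used = 0;

  for (int k = 0; k < n; ++k) {
    double sp = std::sqrt(vx * vx + vz * vz);
    double om = 0.0, thvfly = 0.0;
    if (sp > 0.0) {
      double thv = std::atan2(vz, vx);
      om = sp / d_wall;
      thvfly = thv - th;
    }
    // velocity-projection convention for the controller measurements
    double wx_m = om * std::cos(thvfly);
    double wz_m = om * std::sin(thvfly);

    double cmd = pd.step(wx_m - setpoint);
    if (improved) cmd += pdth.step(-th);
    thd = hal.step(cmd) + zi;
    zi *= zi_decay;

    double f = f_base[k];
    if (improved) f += piwz.step(-wz_m);
    if (f < 0.0) f = 0.0;
    double L = std::cos(th) * f;
    double T = -std::sin(th) * f;

    X[k] = x; Z[k] = z; VX[k] = vx; VZ[k] = vz;
    TH[k] = th; THD[k] = thd;
    F[k] = f; Lv[k] = L; Tv[k] = T;
    WX[k] = -wx_m;  // reported components: flow-opposite convention
    WZ[k] = -wz_m;
    used = k + 1;

    if (std::fabs(th) > guard_theta || sp > guard_speed) {
      diverged = true;
      break;
    }
    if (z <= 0.0) {
      crashed = true;
      if (stop_at_floor) break;
    }

    // semi-implicit Euler: velocities first, then positions and pitch
    vz += Ts * (L - g);
    vx += Ts * T;
    z += Ts * vz;
    x += Ts * vx;
    th += Ts * thd;
  }

  return List::create(
      _["x"] = X, _["z"] = Z, _["vx"] = VX, _["vz"] = VZ,
      _["theta_p"] = TH, _["theta_p_dot"] = THD, _["F_mag"] = F,
      _["L"] = Lv, _["T"] = Tv, _["omega_x"] = WX, _["omega_z"] = WZ,
      _["n_used"] = used, _["diverged"] = diverged, _["crashed"] = crashed);
}
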