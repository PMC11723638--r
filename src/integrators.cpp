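#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fixed-step RK4 integrators for the cart-pendulum ("cup-and-ball") family.
//
// Time-varying inputs are supplied sampled on the *half grid*: a vector of
// length 2*n_steps + 1 holding values at t = k*h/2, so that all four RK4
// stage times (t, t+h/2, t+h) fall on exact samples and no interpolation is
// needed inside the stepper.
//
// State layout for the cart-pendulum: (x, xd, phi, phid).

namespace {

struct PlantParams {
  double mc, mp, l, g;
};

// Accelerations of the cart-pendulum under external horizontal force F.
// linear = true selects the small-angle linearization about phi = 0.
// The implicit xdd/phidd coupling is resolved algebraically:
//   nonlinear: xdd = (mp*l*phid^2*sin + mp*g*sin*cos + F) / (mc + mp*sin^2)
//   linear:    xdd = (mp*g*phi + F) / mc
inline void plant_accel(double xd, double phi, double phid, double F,
                        const PlantParams &p, bool linear,
                        double &xdd, double &phidd) {
  if (linear) {
    xdd = (p.mp * p.g * phi + F) / p.mc;
    phidd = -(p.g * phi + xdd) / p.l;
  } else {
    double sp = std::sin(phi), cp = std::cos(phi);
    xdd = (p.mp * p.l * phid * phid * sp + p.mp * p.g * sp * cp + F) /
          (p.mc + p.mp * sp * sp);
    phidd = -(xdd * cp + p.g * sp) / p.l;
  }
}

inline double ball_force(double phi, double phid, double phidd,
                         const PlantParams &p, bool linear) {
  if (linear) return -p.mp * p.l * phidd;
  return p.mp * p.l * (phid * phid * std::sin(phi) - phidd * std::cos(phi));
}

inline bool finite4(const double *s) {
  return R_finite(s[0]) && R_finite(s[1]) && R_finite(s[2]) && R_finite(s[3]);
}

} // namespace

// Cart-pendulum driven by a prescribed force profile (no impedance).
// [[Rcpp::export]]
List rk4_forced_plant_cpp(NumericVector state0, NumericVector F_half,
                          double h, int n_steps, double mc, double mp,
                          double l, double g, bool linear) {
  if (F_half.size() < 2 * n_steps + 1)
    stop("force profile shorter than integration horizon");
  PlantParams p{mc, mp, l, g};
  int n = n_steps;
  NumericVector x(n + 1), xd(n + 1), phi(n + 1), phid(n + 1);
  double s[4] = {state0[0], state0[1], state0[2], state0[3]};
  int blowup = -1;
  x[0] = s[0]; xd[0] = s[1]; phi[0] = s[2]; phid[0] = s[3];
  for (int i = 0; i < n; ++i) {
    double F1 = F_half[2 * i], F2 = F_half[2 * i + 1], F4 = F_half[2 * i + 2];
    double k1[4], k2[4], k3[4], k4[4], tmp[4], a, b;
    plant_accel(s[1], s[2], s[3], F1, p, linear, a, b);
    k1[0] = s[1]; k1[1] = a; k1[2] = s[3]; k1[3] = b;
    for (int j = 0; j < 4; ++j) tmp[j] = s[j] + 0.5 * h * k1[j];
    plant_accel(tmp[1], tmp[2], tmp[3], F2, p, linear, a, b);
    k2[0] = tmp[1]; k2[1] = a; k2[2] = tmp[3]; k2[3] = b;
    for (int j = 0; j < 4; ++j) tmp[j] = s[j] + 0.5 * h * k2[j];
    plant_accel(tmp[1], tmp[2], tmp[3], F2, p, linear, a, b);
    k3[0] = tmp[1]; k3[1] = a; k3[2] = tmp[3]; k3[3] = b;
    for (int j = 0; j < 4; ++j) tmp[j] = s[j] + h * k3[j];
    plant_accel(tmp[1], tmp[2], tmp[3], F4, p, linear, a, b);
    k4[0] = tmp[1]; k4[1] = a; k4[2] = tmp[3]; k4[3] = b;
    for (int j = 0; j < 4; ++j)
      s[j] += h / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
    if (!finite4(s)) { blowup = i + 1; break; }
    x[i + 1] = s[0]; xd[i + 1] = s[1]; phi[i + 1] = s[2]; phid[i + 1] = s[3];
  }
  int m = (blowup < 0) ? n : blowup - 1;
  NumericVector xdd(n + 1, NA_REAL), phidd(n + 1, NA_REAL),
      Fout(n + 1, NA_REAL), Fball(n + 1, NA_REAL);
  for (int i = 0; i <= m; ++i) {
    double a, b;
    plant_accel(xd[i], phi[i], phid[i], F_half[2 * i], p, linear, a, b);
    xdd[i] = a; phidd[i] = b;
    Fout[i] = F_half[2 * i];
    Fball[i] = ball_force(phi[i], phid[i], b, p, linear);
  }
  return List::create(_["x"] = x, _["xd"] = xd, _["phi"] = phi,
                      _["phid"] = phid, _["xdd"] = xdd, _["phidd"] = phidd,
                      _["F"] = Fout, _["F_ball"] = Fball,
                      _["blowup"] = blowup);
}

// Cart-pendulum coupled to hand impedance:
//   F = Fff + B*(x0d - xd) + K*(x0 - x)
// with the shaped command (x0, x0d) and feedforward Fff on the half grid.
// [[Rcpp::export]]
List rk4_coupled_cpp(NumericVector state0, NumericVector x0_half,
                     NumericVector x0d_half, NumericVector Fff_half, double h,
                     int n_steps, double mc, double mp, double l, double g,
                     double K, double B, bool linear) {
  if (x0_half.size() < 2 * n_steps + 1 || x0d_half.size() < 2 * n_steps + 1 ||
      Fff_half.size() < 2 * n_steps + 1)
    stop("command/feedforward profiles shorter than integration horizon");
  PlantParams p{mc, mp, l, g};
  int n = n_steps;
  NumericVector x(n + 1), xd(n + 1), phi(n + 1), phid(n + 1);
  double s[4] = {state0[0], state0[1], state0[2], state0[3]};
  int blowup = -1;
  x[0] = s[0]; xd[0] = s[1]; phi[0] = s[2]; phid[0] = s[3];
  const double *x0 = x0_half.begin(), *x0d = x0d_half.begin(),
               *ff = Fff_half.begin();
  for (int i = 0; i < n; ++i) {
    int i0 = 2 * i, i1 = 2 * i + 1, i2 = 2 * i + 2;
    double k1[4], k2[4], k3[4], k4[4], tmp[4], a, b, F;
    F = ff[i0] + B * (x0d[i0] - s[1]) + K * (x0[i0] - s[0]);
    plant_accel(s[1], s[2], s[3], F, p, linear, a, b);
    k1[0] = s[1]; k1[1] = a; k1[2] = s[3]; k1[3] = b;
    for (int j = 0; j < 4; ++j) tmp[j] = s[j] + 0.5 * h * k1[j];
    F = ff[i1] + B * (x0d[i1] - tmp[1]) + K * (x0[i1] - tmp[0]);
    plant_accel(tmp[1], tmp[2], tmp[3], F, p, linear, a, b);
    k2[0] = tmp[1]; k2[1] = a; k2[2] = tmp[3]; k2[3] = b;
    for (int j = 0; j < 4; ++j) tmp[j] = s[j] + 0.5 * h * k2[j];
    F = ff[i1] + B * (x0d[i1] - tmp[1]) + K * (x0[i1] - tmp[0]);
    plant_accel(tmp[1], tmp[2], tmp[3], F, p, linear, a, b);
    k3[0] = tmp[1]; k3[1] = a; k3[2] = tmp[3]; k3[3] = b;
    for (int j = 0; j < 4; ++j) tmp[j] = s[j] + h * k3[j];
    F = ff[i2] + B * (x0d[i2] - tmp[1]) + K * (x0[i2] - tmp[0]);
    plant_accel(tmp[1], tmp[2], tmp[3], F, p, linear, a, b);
    k4[0] = tmp[1]; k4[1] = a; k4[2] = tmp[3]; k4[3] = b;
    for (int j = 0; j < 4; ++j)
      s[j] += h / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
    if (!finite4(s)) { blowup = i + 1; break; }
    x[i + 1] = s[0]; xd[i + 1] = s[1]; phi[i + 1] = s[2]; phid[i + 1] = s[3];
  }
  int m = (blowup < 0) ? n : blowup - 1;
  NumericVector xdd(n + 1, NA_REAL), phidd(n + 1, NA_REAL),
      Fout(n + 1, NA_REAL), Fball(n + 1, NA_REAL);
  for (int i = 0; i <= m; ++i) {
    double a, b;
    double F = ff[2 * i] + B * (x0d[2 * i] - xd[i]) + K * (x0[2 * i] - x[i]);
    plant_accel(xd[i], phi[i], phid[i], F, p, linear, a, b);
    xdd[i] = a; phidd[i] = b;
    Fout[i] = F;
    Fball[i] = ball_force(phi[i], phid[i], b, p, linear);
  }
  return List::create(_["x"] = x, _["xd"] = xd, _["phi"] = phi,
                      _["phid"] = phid, _["xdd"] = xdd, _["phidd"] = phidd,
                      _["F"] = Fout, _["F_ball"] = Fball,
                      _["blowup"] = blowup);
}

// Mass-spring-damper tracking a commanded trajectory:
//   mass*xdd + Beff*(xd - x0d) + Keff*(x - x0) = 0
// Used to generate desired kinematics of the 2nd-order internal models.
// [[Rcpp::export]]
List rk4_msd_cpp(NumericVector state0, NumericVector x0_half,
                 NumericVector x0d_half, double h, int n_steps, double mass,
                 double Keff, double Beff) {
  if (x0_half.size() < 2 * n_steps + 1 || x0d_half.size() < 2 * n_steps + 1)
    stop("command profiles shorter than integration horizon");
  int n = n_steps;
  NumericVector x(n + 1), xd(n + 1);
  double s0 = state0[0], s1 = state0[1];
  int blowup = -1;
  x[0] = s0; xd[0] = s1;
  const double *x0 = x0_half.begin(), *x0d = x0d_half.begin();
  for (int i = 0; i < n; ++i) {
    int i0 = 2 * i, i1 = 2 * i + 1, i2 = 2 * i + 2;
    double k1p, k1v, k2p, k2v, k3p, k3v, k4p, k4v, tp, tv;
    k1p = s1;
    k1v = (Keff * (x0[i0] - s0) + Beff * (x0d[i0] - s1)) / mass;
    tp = s0 + 0.5 * h * k1p; tv = s1 + 0.5 * h * k1v;
    k2p = tv; k2v = (Keff * (x0[i1] - tp) + Beff * (x0d[i1] - tv)) / mass;
    tp = s0 + 0.5 * h * k2p; tv = s1 + 0.5 * h * k2v;
    k3p = tv; k3v = (Keff * (x0[i1] - tp) + Beff * (x0d[i1] - tv)) / mass;
    tp = s0 + h * k3p; tv = s1 + h * k3v;
    k4p = tv; k4v = (Keff * (x0[i2] - tp) + Beff * (x0d[i2] - tv)) / mass;
    s0 += h / 6.0 * (k1p + 2.0 * k2p + 2.0 * k3p + k4p);
    s1 += h / 6.0 * (k1v + 2.0 * k2v + 2.0 * k3v + k4v);
    if (!(R_finite(s0) && R_finite(s1))) { blowup = i + 1; break; }
    x[i + 1] = s0; xd[i + 1] = s1;
  }
  int m = (blowup < 0) ? n : blowup - 1;
  NumericVector xdd(n + 1, NA_REAL);
  for (int i = 0; i <= m; ++i)
    xdd[i] = (Keff * (x0[2 * i] - x[i]) + Beff * (x0d[2 * i] - xd[i])) / mass;
  return List::create(_["x"] = x, _["xd"] = xd, _["xdd"] = xdd,
                      _["blowup"] = blowup);
}

// Pendulum driven kinematically by a commanded cart acceleration x0dd:
//   linear:    phidd = -(g*phi   + x0dd) / l
//   nonlinear: phidd = -(g*sin(phi) + x0dd*cos(phi)) / l
// With x0dd = 0 and linear = false this is the free undamped pendulum used
// by the residual-ball-angle metric.
// [[Rcpp::export]]
List rk4_pendulum_cpp(NumericVector state0, NumericVector x0dd_half, double h,
                      int n_steps, double l, double g, bool linear) {
  if (x0dd_half.size() < 2 * n_steps + 1)
    stop("acceleration profile shorter than integration horizon");
  int n = n_steps;
  NumericVector phi(n + 1), phid(n + 1);
  double s0 = state0[0], s1 = state0[1];
  int blowup = -1;
  phi[0] = s0; phid[0] = s1;
  const double *a0 = x0dd_half.begin();
  auto acc = [&](double ph, double adrv) {
    if (linear) return -(g * ph + adrv) / l;
    return -(g * std::sin(ph) + adrv * std::cos(ph)) / l;
  };
  for (int i = 0; i < n; ++i) {
    int i0 = 2 * i, i1 = 2 * i + 1, i2 = 2 * i + 2;
    double k1p = s1, k1v = acc(s0, a0[i0]);
    double tp = s0 + 0.5 * h * k1p, tv = s1 + 0.5 * h * k1v;
    double k2p = tv, k2v = acc(tp, a0[i1]);
    tp = s0 + 0.5 * h * k2p; tv = s1 + 0.5 * h * k2v;
    double k3p = tv, k3v = acc(tp, a0[i1]);
    tp = s0 + h * k3p; tv = s1 + h * k3v;
    double k4p = tv, k4v = acc(tp, a0[i2]);
    s0 += h / 6.0 * (k1p + 2.0 * k2p + 2.0 * k3p + k4p);
    s1 += h / 6.0 * (k1v + 2.0 * k2v + 2.0 * k3v + k4v);
    if (!(R_finite(s0) && R_finite(s1))) { blowup = i + 1; break; }
    phi[i + 1] = s0; phid[i + 1] = s1;
  }
  int m = (blowup < 0) ? n : blowup - 1;
  NumericVector phidd(n + 1, NA_REAL);
  for (int i = 0; i <= m; ++i) phidd[i] = acc(phi[i], a0[2 * i]);
  return List::create(_["phi"] = phi, _["phid"] = phid, _["phidd"] = phidd,
                      _["blowup"] = blowup);
}
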