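// Fast inner loop of the tendon-driven eye plant.
//
// State: Euler-Rodrigues rotation vector r (rad/2) and angular velocity w
// (rad/s) in the head frame. Six straight cables pull at insertions on the
// globe surface; tension is a pull-only linear spring on (path stretch +
// commanded shortening). Rigid-body dynamics: I(r) wdot = 1000*tau - w x
// (I(r) w), with I in kg mm^2 and tau in N mm (the factor 1000 converts the
// mixed mm units to rad/s^2). Orientation advances through the exact
// kinematic map 2 rdot = w + w x r + (w.r) r. Integration: classical RK4 at
// the 1 ms sampling step with zero-order-hold controls.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct Plant {
  double radius, k, Tpre, damping;
  double ins[6][3];
  double att[6][3];
  double L0[6];
  double uh[6]; // absolute holding command at the (0,0,0) fixation
  double Ieye[3];
};

static inline void cross3(const double* a, const double* b, double* o) {
  o[0] = a[1] * b[2] - a[2] * b[1];
  o[1] = a[2] * b[0] - a[0] * b[2];
  o[2] = a[0] * b[1] - a[1] * b[0];
}

// R = I + 2/(1+|r|^2) * ([r]x + [r]x^2), row-major
static void rotmat(const double r[3], double R[3][3]) {
  double s = 2.0 / (1.0 + r[0] * r[0] + r[1] * r[1] + r[2] * r[2]);
  double x = r[0], y = r[1], z = r[2];
  R[0][0] = 1 + s * (-y * y - z * z);
  R[0][1] = s * (-z + x * y);
  R[0][2] = s * (y + x * z);
  R[1][0] = s * (z + x * y);
  R[1][1] = 1 + s * (-x * x - z * z);
  R[1][2] = s * (-x + y * z);
  R[2][0] = s * (-y + x * z);
  R[2][1] = s * (x + y * z);
  R[2][2] = 1 + s * (-x * x - y * y);
}

static void solve3(const double A[3][3], const double b[3], double x[3]) {
  double det =
      A[0][0] * (A[1][1] * A[2][2] - A[1][2] * A[2][1]) -
      A[0][1] * (A[1][0] * A[2][2] - A[1][2] * A[2][0]) +
      A[0][2] * (A[1][0] * A[2][1] - A[1][1] * A[2][0]);
  double inv = 1.0 / det;
  x[0] = inv * (b[0] * (A[1][1] * A[2][2] - A[1][2] * A[2][1]) -
                A[0][1] * (b[1] * A[2][2] - A[1][2] * b[2]) +
                A[0][2] * (b[1] * A[2][1] - A[1][1] * b[2]));
  x[1] = inv * (A[0][0] * (b[1] * A[2][2] - A[1][2] * b[2]) -
                b[0] * (A[1][0] * A[2][2] - A[1][2] * A[2][0]) +
                A[0][2] * (A[1][0] * b[2] - b[1] * A[2][0]));
  x[2] = inv * (A[0][0] * (A[1][1] * b[2] - b[1] * A[2][1]) -
                A[0][1] * (A[1][0] * b[2] - b[1] * A[2][0]) +
                b[0] * (A[1][0] * A[2][1] - A[1][1] * A[2][0]));
}

// time derivative of (r, w); u are commands relative to the (0,0,0) holding
// command; tensions optionally reported
static void deriv(const Plant& P, const double r[3], const double w[3],
                  const double u[6], double rdot[3], double wdot[3],
                  double* Tout) {
  double R[3][3];
  rotmat(r, R);
  double tau[3] = {-P.damping * w[0], -P.damping * w[1], -P.damping * w[2]};
  for (int i = 0; i < 6; ++i) {
    double p[3], v[3];
    for (int a = 0; a < 3; ++a)
      p[a] = P.radius * (R[a][0] * P.ins[i][0] + R[a][1] * P.ins[i][1] +
                         R[a][2] * P.ins[i][2]);
    for (int a = 0; a < 3; ++a) v[a] = P.att[i][a] - p[a];
    double L = std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
    double T = P.Tpre + P.k * ((L - P.L0[i]) + P.uh[i] + u[i]);
    if (T < 0) T = 0;
    if (Tout) Tout[i] = T;
    double f = T / L;
    double fd[3] = {f * v[0], f * v[1], f * v[2]};
    double tq[3];
    cross3(p, fd, tq);
    tau[0] += tq[0]; tau[1] += tq[1]; tau[2] += tq[2];
  }
  // head-frame inertia: Ih = R diag(Ieye) R^T
  double Ih[3][3];
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b)
      Ih[a][b] = R[a][0] * P.Ieye[0] * R[b][0] +
                 R[a][1] * P.Ieye[1] * R[b][1] +
                 R[a][2] * P.Ieye[2] * R[b][2];
  double h[3] = {Ih[0][0] * w[0] + Ih[0][1] * w[1] + Ih[0][2] * w[2],
                 Ih[1][0] * w[0] + Ih[1][1] * w[1] + Ih[1][2] * w[2],
                 Ih[2][0] * w[0] + Ih[2][1] * w[1] + Ih[2][2] * w[2]};
  double gy[3];
  cross3(w, h, gy);
  double rhs[3] = {1000.0 * tau[0] - gy[0], 1000.0 * tau[1] - gy[1],
                   1000.0 * tau[2] - gy[2]};
  solve3(Ih, rhs, wdot);
  double wxr[3];
  cross3(w, r, wxr);
  double wr = w[0] * r[0] + w[1] * r[1] + w[2] * r[2];
  for (int a = 0; a < 3; ++a)
    rdot[a] = 0.5 * (w[a] + wxr[a] + wr * r[a]);
}

static void rk4_step(const Plant& P, double r[3], double w[3],
                     const double u[6], double dt) {
  double k1r[3], k1w[3], k2r[3], k2w[3], k3r[3], k3w[3], k4r[3], k4w[3];
  double rt[3], wt[3];
  deriv(P, r, w, u, k1r, k1w, nullptr);
  for (int a = 0; a < 3; ++a) { rt[a] = r[a] + 0.5 * dt * k1r[a]; wt[a] = w[a] + 0.5 * dt * k1w[a]; }
  deriv(P, rt, wt, u, k2r, k2w, nullptr);
  for (int a = 0; a < 3; ++a) { rt[a] = r[a] + 0.5 * dt * k2r[a]; wt[a] = w[a] + 0.5 * dt * k2w[a]; }
  deriv(P, rt, wt, u, k3r, k3w, nullptr);
  for (int a = 0; a < 3; ++a) { rt[a] = r[a] + dt * k3r[a]; wt[a] = w[a] + dt * k3w[a]; }
  deriv(P, rt, wt, u, k4r, k4w, nullptr);
  for (int a = 0; a < 3; ++a) {
    r[a] += dt / 6.0 * (k1r[a] + 2 * k2r[a] + 2 * k3r[a] + k4r[a]);
    w[a] += dt / 6.0 * (k1w[a] + 2 * k2w[a] + 2 * k3w[a] + k4w[a]);
  }
}

static Plant make_plant(NumericMatrix ins, NumericMatrix att, double radius,
                        NumericVector L0, NumericVector u_hold,
                        double stiffness, double pretension,
                        NumericVector inertia, double damping) {
  Plant P;
  P.radius = radius; P.k = stiffness; P.Tpre = pretension; P.damping = damping;
  for (int i = 0; i < 6; ++i) {
    for (int a = 0; a < 3; ++a) {
      P.ins[i][a] = ins(i, a);
      P.att[i][a] = att(i, a);
    }
    P.L0[i] = L0[i];
    P.uh[i] = u_hold[i];
  }
  for (int a = 0; a < 3; ++a) P.Ieye[a] = inertia[a];
  return P;
}

// [[Rcpp::export]]
List cpp_simulate(NumericMatrix controls, NumericVector r0, NumericVector w0,
                  NumericMatrix ins, NumericMatrix att, double radius,
                  NumericVector L0, NumericVector u_hold, double stiffness,
                  double pretension, NumericVector inertia, double damping,
                  double dt) {
  int N = controls.ncol();
  Plant P = make_plant(ins, att, radius, L0, u_hold, stiffness, pretension,
                       inertia, damping);
  NumericMatrix rout(N + 1, 3), wout(N + 1, 3), rdout(N + 1, 3),
      Tout(N + 1, 6);
  double r[3] = {r0[0], r0[1], r0[2]}, w[3] = {w0[0], w0[1], w0[2]};
  double rd[3], wd[3], Tk[6], u[6];
  for (int t = 0; t <= N; ++t) {
    int tc = (t < N) ? t : N - 1;
    for (int i = 0; i < 6; ++i) u[i] = controls(i, tc);
    deriv(P, r, w, u, rd, wd, Tk);
    for (int a = 0; a < 3; ++a) {
      rout(t, a) = r[a]; wout(t, a) = w[a]; rdout(t, a) = rd[a];
    }
    for (int i = 0; i < 6; ++i) Tout(t, i) = Tk[i];
    if (t < N) {
      rk4_step(P, r, w, u, dt);
      if (!std::isfinite(r[0]) || !std::isfinite(r[1]) ||
          !std::isfinite(r[2]) || !std::isfinite(w[0]) ||
          !std::isfinite(w[1]) || !std::isfinite(w[2]))
        stop("plant state became non-finite at t = %d ms", t + 1);
    }
  }
  return List::create(_["r"] = rout, _["w"] = wout, _["rdot"] = rdout,
                      _["tension"] = Tout);
}

// Core of the controller objective: expand per-muscle knots to a 1 ms
// zero-order-hold signal by linear interpolation, simulate, and accumulate
// the raw accuracy and energy integrals.
static void objective_core(const Plant& P, const double* knots, int nk,
                           const double* knot_t, int n_ms,
                           const double* u_prev, const double* r0,
                           const double* w0, const double* goal,
                           double w_omega, double dt, double* JA,
                           double* JE) {
  double r[3] = {r0[0], r0[1], r0[2]}, w[3] = {w0[0], w0[1], w0[2]};
  double u[6], ulast[6];
  for (int i = 0; i < 6; ++i) ulast[i] = u_prev[i];
  *JE = 0.0;
  int seg = 0;
  for (int t = 0; t < n_ms; ++t) {
    while (seg + 1 < nk - 1 && knot_t[seg + 1] <= t) ++seg;
    double t0 = knot_t[seg], t1 = knot_t[seg + 1];
    double a = (t - t0) / (t1 - t0);
    for (int i = 0; i < 6; ++i) {
      u[i] = (1 - a) * knots[seg * 6 + i] + a * knots[(seg + 1) * 6 + i];
      double du = u[i] - ulast[i];
      *JE += du * du / dt;
      ulast[i] = u[i];
    }
    rk4_step(P, r, w, u, dt);
    if (!std::isfinite(r[0]) || !std::isfinite(w[0])) {
      *JA = 1e12; *JE = 1e12;
      return;
    }
  }
  *JA = 0.0;
  for (int a = 0; a < 3; ++a) {
    double er = r[a] - goal[a];
    *JA += er * er + w_omega * w[a] * w[a];
  }
}

// [[Rcpp::export]]
NumericVector cpp_objective(NumericMatrix knots, NumericVector knot_t,
                            int n_ms, NumericVector u_prev, NumericVector r0,
                            NumericVector w0, NumericVector goal,
                            double w_omega, NumericMatrix ins,
                            NumericMatrix att, double radius,
                            NumericVector L0, NumericVector u_hold,
                            double stiffness, double pretension,
                            NumericVector inertia, double damping,
                            double dt) {
  Plant P = make_plant(ins, att, radius, L0, u_hold, stiffness, pretension,
                       inertia, damping);
  double JA, JE;
  objective_core(P, knots.begin(), knots.ncol(), knot_t.begin(), n_ms,
                 u_prev.begin(), r0.begin(), w0.begin(), goal.begin(),
                 w_omega, dt, &JA, &JE);
  return NumericVector::create(JA, JE);
}

// Weighted objective plus forward-difference gradient in the knot values,
// computed entirely in compiled code (one base evaluation + one per knot).
// [[Rcpp::export]]
List cpp_objective_grad(NumericMatrix knots, NumericVector knot_t, int n_ms,
                        NumericVector u_prev, NumericVector r0,
                        NumericVector w0, NumericVector goal, double w_omega,
                        double lambda_a, double lambda_e, double eps,
                        NumericMatrix ins, NumericMatrix att, double radius,
                        NumericVector L0, NumericVector u_hold,
                        double stiffness, double pretension,
                        NumericVector inertia, double damping, double dt) {
  int nk = knots.ncol();
  int n = 6 * nk;
  Plant P = make_plant(ins, att, radius, L0, u_hold, stiffness, pretension,
                       inertia, damping);
  std::vector<double> kn(knots.begin(), knots.end());
  double JA, JE;
  objective_core(P, kn.data(), nk, knot_t.begin(), n_ms, u_prev.begin(),
                 r0.begin(), w0.begin(), goal.begin(), w_omega, dt, &JA, &JE);
  double f0 = lambda_a * JA + lambda_e * JE;
  NumericVector grad(n);
  for (int j = 0; j < n; ++j) {
    double saved = kn[j];
    kn[j] = saved + eps;
    objective_core(P, kn.data(), nk, knot_t.begin(), n_ms, u_prev.begin(),
                   r0.begin(), w0.begin(), goal.begin(), w_omega, dt, &JA,
                   &JE);
    kn[j] = saved;
    grad[j] = (lambda_a * JA + lambda_e * JE - f0) / eps;
  }
  return List::create(_["value"] = f0, _["grad"] = grad);
}
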