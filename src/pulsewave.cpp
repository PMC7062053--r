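// 1D elastic-tube pulse-wave solver (area-flow formulation) with a
// two-element Windkessel outlet and an optional distributed mid-tube
// outflow sink. Two-step (Richtmyer) Lax-Wendroff on a uniform node grid.
//
// Tube law: p(A) = beta/A0 * (sqrt(A) - sqrt(A0)), beta = sqrt(pi) * E * h,
// whose linearized wave speed at A0 is exactly c0 = sqrt(E*h / (2*rho*r0)).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Tube {
  double A0, beta, rho, kc, c0, mu;
  double p(double A) const { return beta / A0 * (std::sqrt(A) - std::sqrt(A0)); }
  double dpdA(double A) const { return beta / (2.0 * A0 * std::sqrt(A)); }
  double c(double A) const { return kc * std::sqrt(std::sqrt(A)); }
};

// inlet boundary: solve A with prescribed Q and backward characteristic W2
double solve_inlet_A(const Tube &tb, double W2, double Qin, double Aguess) {
  double A = Aguess;
  for (int it = 0; it < 50; ++it) {
    double c = tb.c(A);
    double u = W2 + 4.0 * (c - tb.c0);
    double F = A * u - Qin;
    double dF = u + c;  // d/dA [A*(W2+4(c-c0))] = u + 4*A*c'(A) = u + c
    double step = F / dF;
    A -= step;
    if (A < 0.05 * tb.A0) A = 0.05 * tb.A0;
    if (A > 20.0 * tb.A0) A = 20.0 * tb.A0;
    if (std::fabs(step) < 1e-14 * tb.A0) break;
  }
  return A;
}

// outlet boundary: forward characteristic W1 + implicit-Euler Windkessel
double solve_outlet_A(const Tube &tb, double W1, double Pold, double Rwk,
                      double Cwk, double dt, double Aguess) {
  double fac = 1.0 + dt / (Rwk * Cwk);
  double A = Aguess;
  for (int it = 0; it < 60; ++it) {
    double c = tb.c(A);
    double u = W1 - 4.0 * (c - tb.c0);
    double G = tb.p(A) - (Pold + dt / Cwk * A * u) / fac;
    double dG = tb.dpdA(A) - (dt / Cwk) * (u - c) / fac;
    double step = G / dG;
    A -= step;
    if (A < 0.05 * tb.A0) A = 0.05 * tb.A0;
    if (A > 20.0 * tb.A0) A = 20.0 * tb.A0;
    if (std::fabs(step) < 1e-14 * tb.A0) break;
  }
  return A;
}


// implicit (backward-Euler) diffusion step for the viscoelastic wall term:
// solves (I - dt*D*d2/dx2) Qnew = Q with boundary values held fixed.
void implicit_diffuse(std::vector<double> &Q, double lam, int n,
                      std::vector<double> &cp, std::vector<double> &dp) {
  cp[0] = 0.0; dp[0] = Q[0];
  for (int i = 1; i < n - 1; ++i) {
    double m = 1.0 + 2.0 * lam + lam * cp[i - 1];
    cp[i] = -lam / m;
    dp[i] = (Q[i] + lam * dp[i - 1]) / m;
  }
  dp[n - 1] = Q[n - 1];
  for (int i = n - 2; i >= 1; --i) Q[i] = dp[i] - cp[i] * Q[i + 1];
}

} // namespace

// [[Rcpp::export]]
List solve_tube_1d_cpp(int n_nodes, double L, double r0, double h, double E,
                       double rho, double mu,
                       NumericVector inlet_t, NumericVector inlet_q,
                       double period, double Rwk, double Cwk, double P_init,
                       int max_cycles, double cycle_tol, double cfl,
                       double dt_user, double sink_x0, double sink_x1,
                       double sink_G, double visc_D, double arr_frac, int snap_nt) {
  if (n_nodes < 10) stop("need at least 10 grid nodes");
  if (Rwk <= 0.0 || Cwk <= 0.0) stop("Windkessel R and C must be positive");
  Tube tb;
  tb.A0 = M_PI * r0 * r0;
  tb.beta = std::sqrt(M_PI) * E * h;
  tb.rho = rho;
  tb.mu = mu;
  tb.kc = std::sqrt(tb.beta / (2.0 * rho * tb.A0));
  tb.c0 = tb.kc * std::sqrt(std::sqrt(tb.A0));

  const double dx = L / (n_nodes - 1);
  double qmax = 0.0;
  for (double q : inlet_q) qmax = std::max(qmax, std::fabs(q));
  const double u_est = 3.0 * qmax / tb.A0; // generous convective margin
  const double dt_cfl = dx / (tb.c0 + u_est);
  double dt = (dt_user > 0.0) ? dt_user : cfl * dt_cfl;
  if (dt > dt_cfl) {
    stop("CFL violation: dt = %g s exceeds dx/(c0+u_max) = %g s; use dt <= %g",
         dt, dt_cfl, dt_cfl);
  }
  int spc = (int)std::ceil(period / dt);
  dt = period / spc; // align steps with the cycle

  // per-step inlet flow over one cycle (periodic linear interpolation)
  std::vector<double> qin(spc);
  int nin = inlet_t.size();
  for (int s = 0; s < spc; ++s) {
    double t = s * dt - std::floor(s * dt / period) * period;
    int j = 0;
    while (j < nin - 1 && inlet_t[j + 1] <= t) ++j;
    double t0 = inlet_t[j];
    double t1 = (j == nin - 1) ? inlet_t[0] + period : inlet_t[j + 1];
    double q0 = inlet_q[j];
    double q1 = (j == nin - 1) ? inlet_q[0] : inlet_q[j + 1];
    double w = (t1 > t0) ? (t - t0) / (t1 - t0) : 0.0;
    qin[s] = q0 + w * (q1 - q0);
  }

  // sink conductance per unit length over the sink interval
  std::vector<double> g(n_nodes, 0.0);
  if (sink_G > 0.0 && sink_x1 > sink_x0) {
    double Ls = (sink_x1 - sink_x0) * L;
    for (int i = 0; i < n_nodes; ++i) {
      double x = i * dx;
      if (x >= sink_x0 * L && x <= sink_x1 * L) g[i] = sink_G / Ls;
    }
  }

  // warm start at the diastolic operating point: steady base flow, tube
  // pressurized against the charged Windkessel, so the only cold-start
  // transient is the systolic upstroke itself
  double q_base0 = inlet_q[0];
  double P_dia = (P_init > 0.0) ? P_init : Rwk * q_base0;
  double sqA_dia = std::sqrt(tb.A0) + P_dia * tb.A0 / tb.beta;
  double A_dia = sqA_dia * sqA_dia;
  std::vector<double> A(n_nodes, A_dia), Q(n_nodes, q_base0);
  std::vector<double> tri_c(n_nodes), tri_d(n_nodes);

  // first-arrival detection (cold start): threshold just above the initial
  // base flow so the crossing tracks the causal systolic wavefront
  double q_base = qin[0];
  double q_pk = 0.0;
  for (double q : qin) q_pk = std::max(q_pk, q);
  double arr_thresh = q_base + arr_frac * (q_pk - q_base);
  std::vector<double> arr(n_nodes, -1.0);
  std::vector<double> Ah(n_nodes - 1), Qh(n_nodes - 1);
  std::vector<double> F1(n_nodes), F2(n_nodes), S1(n_nodes), S2(n_nodes);
  double Pwk = P_dia;

  NumericVector t_rec(spc), qin_rec(spc), qout_rec(spc), pin_rec(spc),
      pout_rec(spc);
  double qm_in = 0, qm_out = 0, qm_sink = 0;
  bool converged = false;
  int cycles_run = 0;
  std::vector<double> pout_prev(spc, 0.0), pout_this(spc, 0.0);

  const double nu8pi = 8.0 * M_PI * mu / rho;
  const double b3 = tb.beta / (3.0 * rho * tb.A0);

  auto flux = [&](int i) {
    F1[i] = Q[i];
    F2[i] = Q[i] * Q[i] / A[i] + b3 * A[i] * std::sqrt(A[i]);
  };
  auto source = [&](int i) {
    S1[i] = -g[i] * tb.p(A[i]);
    S2[i] = -nu8pi * Q[i] / A[i];
  };

  int total_cycles = max_cycles;
  for (int cyc = 0; cyc < total_cycles; ++cyc) {
    qm_in = qm_out = qm_sink = 0.0;
    for (int s = 0; s < spc; ++s) {
      for (int i = 0; i < n_nodes; ++i) { flux(i); source(i); }
      // half step at interfaces
      for (int i = 0; i < n_nodes - 1; ++i) {
        Ah[i] = 0.5 * (A[i] + A[i + 1]) - dt / (2 * dx) * (F1[i + 1] - F1[i]) +
                0.25 * dt * (S1[i] + S1[i + 1]);
        Qh[i] = 0.5 * (Q[i] + Q[i + 1]) - dt / (2 * dx) * (F2[i + 1] - F2[i]) +
                0.25 * dt * (S2[i] + S2[i + 1]);
        if (Ah[i] < 0.05 * tb.A0) Ah[i] = 0.05 * tb.A0;
      }
      // characteristic info from old interior state
      double W2 = Q[1] / A[1] - 4.0 * (tb.c(A[1]) - tb.c0);
      double W1 = Q[n_nodes - 2] / A[n_nodes - 2] +
                  4.0 * (tb.c(A[n_nodes - 2]) - tb.c0);
      // full step, interior
      for (int i = 1; i < n_nodes - 1; ++i) {
        double f1l = Qh[i - 1];
        double f1r = Qh[i];
        double f2l = Qh[i - 1] * Qh[i - 1] / Ah[i - 1] + b3 * Ah[i - 1] * std::sqrt(Ah[i - 1]);
        double f2r = Qh[i] * Qh[i] / Ah[i] + b3 * Ah[i] * std::sqrt(Ah[i]);
        double s1h = -0.5 * (g[i - 1] + g[i]) * tb.p(Ah[i - 1]) * 0.5 -
                     0.5 * (g[i] + g[i + 1]) * tb.p(Ah[i]) * 0.5;
        double s2h = -nu8pi * 0.5 * (Qh[i - 1] / Ah[i - 1] + Qh[i] / Ah[i]);
        A[i] += -dt / dx * (f1r - f1l) + dt * s1h;
        Q[i] += -dt / dx * (f2r - f2l) + dt * s2h;
        if (A[i] < 0.05 * tb.A0) A[i] = 0.05 * tb.A0;
      }
      // boundaries
      double Qin_now = qin[(s + 1) % spc];
      A[0] = solve_inlet_A(tb, W2, Qin_now, A[0]);
      Q[0] = Qin_now;
      double Aout = solve_outlet_A(tb, W1, Pwk, Rwk, Cwk, dt, A[n_nodes - 1]);
      A[n_nodes - 1] = Aout;
      Q[n_nodes - 1] = Aout * (W1 - 4.0 * (tb.c(Aout) - tb.c0));
      Pwk = tb.p(Aout);
      if (visc_D > 0.0)
        implicit_diffuse(Q, dt * visc_D / (dx * dx), n_nodes, tri_c, tri_d);

      if (cyc == 0) {
        double tnow = (s + 1) * dt;
        for (int i = 0; i < n_nodes; ++i)
          if (arr[i] < 0.0 && Q[i] >= arr_thresh) arr[i] = tnow;
      }

      if (!std::isfinite(A[n_nodes / 2]) || !std::isfinite(Q[n_nodes / 2]))
        stop("pulse-wave solver blew up (non-finite state); reduce dt or check parameters");

      // record this cycle's probe values
      t_rec[s] = (s + 1) * dt;
      qin_rec[s] = Q[0];
      qout_rec[s] = Q[n_nodes - 1];
      pin_rec[s] = tb.p(A[0]);
      pout_rec[s] = Pwk;
      pout_this[s] = Pwk;
      qm_in += Q[0];
      qm_out += Q[n_nodes - 1];
      double qs = 0.0;
      for (int i = 0; i < n_nodes; ++i)
        if (g[i] > 0.0) qs += g[i] * tb.p(A[i]) * dx;
      qm_sink += qs;
    }
    cycles_run = cyc + 1;
    if (cyc >= 1) {
      double num = 0, den = 0;
      for (int s = 0; s < spc; ++s) {
        double d = pout_this[s] - pout_prev[s];
        num += d * d;
        den += pout_prev[s] * pout_prev[s];
      }
      if (std::sqrt(num / (den + 1e-30)) < cycle_tol) { converged = true; }
    }
    pout_prev = pout_this;
    if (converged) break;
  }
  qm_in /= spc; qm_out /= spc; qm_sink /= spc;

  // snapshot pass: one extra cycle at periodic steady state
  int stride = std::max(1, spc / std::max(1, snap_nt));
  int nsnap = spc / stride;
  NumericMatrix snapQ(n_nodes, nsnap), snapP(n_nodes, nsnap), snapA(n_nodes, nsnap);
  NumericVector snap_t(nsnap);
  int ks = 0;
  for (int s = 0; s < spc; ++s) {
    for (int i = 0; i < n_nodes; ++i) { flux(i); source(i); }
    for (int i = 0; i < n_nodes - 1; ++i) {
      Ah[i] = 0.5 * (A[i] + A[i + 1]) - dt / (2 * dx) * (F1[i + 1] - F1[i]) +
              0.25 * dt * (S1[i] + S1[i + 1]);
      Qh[i] = 0.5 * (Q[i] + Q[i + 1]) - dt / (2 * dx) * (F2[i + 1] - F2[i]) +
              0.25 * dt * (S2[i] + S2[i + 1]);
      if (Ah[i] < 0.05 * tb.A0) Ah[i] = 0.05 * tb.A0;
    }
    double W2 = Q[1] / A[1] - 4.0 * (tb.c(A[1]) - tb.c0);
    double W1 = Q[n_nodes - 2] / A[n_nodes - 2] +
                4.0 * (tb.c(A[n_nodes - 2]) - tb.c0);
    for (int i = 1; i < n_nodes - 1; ++i) {
      double f1l = Qh[i - 1], f1r = Qh[i];
      double f2l = Qh[i - 1] * Qh[i - 1] / Ah[i - 1] + b3 * Ah[i - 1] * std::sqrt(Ah[i - 1]);
      double f2r = Qh[i] * Qh[i] / Ah[i] + b3 * Ah[i] * std::sqrt(Ah[i]);
      double s2h = -nu8pi * 0.5 * (Qh[i - 1] / Ah[i - 1] + Qh[i] / Ah[i]);
      double s1h = -g[i] * tb.p(A[i]);
      A[i] += -dt / dx * (f1r - f1l) + dt * s1h;
      Q[i] += -dt / dx * (f2r - f2l) + dt * s2h;
      if (A[i] < 0.05 * tb.A0) A[i] = 0.05 * tb.A0;
    }
    double Qin_now = qin[(s + 1) % spc];
    A[0] = solve_inlet_A(tb, W2, Qin_now, A[0]);
    Q[0] = Qin_now;
    double Aout = solve_outlet_A(tb, W1, Pwk, Rwk, Cwk, dt, A[n_nodes - 1]);
    A[n_nodes - 1] = Aout;
    Q[n_nodes - 1] = Aout * (W1 - 4.0 * (tb.c(Aout) - tb.c0));
    Pwk = tb.p(Aout);
    if (visc_D > 0.0)
      implicit_diffuse(Q, dt * visc_D / (dx * dx), n_nodes, tri_c, tri_d);
    t_rec[s] = (s + 1) * dt;
    qin_rec[s] = Q[0];
    qout_rec[s] = Q[n_nodes - 1];
    pin_rec[s] = tb.p(A[0]);
    pout_rec[s] = Pwk;
    if (s % stride == 0 && ks < nsnap) {
      snap_t[ks] = s * dt;
      for (int i = 0; i < n_nodes; ++i) {
        snapQ(i, ks) = Q[i];
        snapP(i, ks) = tb.p(A[i]);
        snapA(i, ks) = A[i];
      }
      ++ks;
    }
  }
  NumericVector snap_x(n_nodes);
  for (int i = 0; i < n_nodes; ++i) snap_x[i] = i * dx;

  return List::create(
      _["dt"] = dt, _["steps_per_cycle"] = spc, _["cycles_run"] = cycles_run,
      _["converged"] = converged, _["c0"] = tb.c0,
      _["time"] = t_rec, _["q_in"] = qin_rec, _["q_out"] = qout_rec,
      _["p_in"] = pin_rec, _["p_out"] = pout_rec,
      _["qmean_in"] = qm_in, _["qmean_out"] = qm_out, _["qmean_sink"] = qm_sink,
      _["arrival_t"] = NumericVector(arr.begin(), arr.end()),
      _["arrival_thresh"] = arr_thresh,
      _["snap_x"] = snap_x, _["snap_t"] = snap_t,
      _["snap_Q"] = snapQ, _["snap_P"] = snapP, _["snap_A"] = snapA);
}

// Project points onto a tube geometry: nearest centerline station, local
// frame coordinates, interpolated arc length and lumen radius.
// [[Rcpp::export]]
List project_to_tube_cpp(NumericMatrix points, NumericMatrix centerline,
                         NumericMatrix tangent, NumericMatrix normal,
                         NumericMatrix binormal, NumericVector arclength,
                         NumericVector radius) {
  int m = points.nrow(), n = centerline.nrow();
  IntegerVector station(m);
  NumericVector s_out(m), x1(m), x2(m), rho(m), r_loc(m);
  LogicalVector inside(m);
  double L = arclength[n - 1];
  for (int p = 0; p < m; ++p) {
    double px = points(p, 0), py = points(p, 1), pz = points(p, 2);
    double best = R_PosInf;
    int bi = 0;
    for (int i = 0; i < n; ++i) {
      double dx = px - centerline(i, 0), dy = py - centerline(i, 1),
             dz = pz - centerline(i, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; bi = i; }
    }
    double dx = px - centerline(bi, 0), dy = py - centerline(bi, 1),
           dz = pz - centerline(bi, 2);
    double sl = dx * tangent(bi, 0) + dy * tangent(bi, 1) + dz * tangent(bi, 2);
    double a = dx * normal(bi, 0) + dy * normal(bi, 1) + dz * normal(bi, 2);
    double b = dx * binormal(bi, 0) + dy * binormal(bi, 1) + dz * binormal(bi, 2);
    double s = arclength[bi] + sl;
    double rh = std::sqrt(a * a + b * b);
    // linear radius interpolation in s
    double r;
    if (s <= arclength[0]) r = radius[0];
    else if (s >= L) r = radius[n - 1];
    else {
      int j = bi;
      if (s < arclength[j]) { while (j > 0 && s < arclength[j]) --j; }
      else { while (j < n - 1 && s > arclength[j + 1]) ++j; }
      double w = (s - arclength[j]) / (arclength[j + 1] - arclength[j]);
      r = radius[j] + w * (radius[j + 1] - radius[j]);
    }
    station[p] = bi + 1;
    s_out[p] = s;
    x1[p] = a;
    x2[p] = b;
    rho[p] = rh;
    r_loc[p] = r;
    inside[p] = (s >= -1e-9 && s <= L + 1e-9 && rh <= r + 1e-9);
  }
  return List::create(_["station"] = station, _["s"] = s_out, _["x1"] = x1,
                      _["x2"] = x2, _["rho"] = rho, _["r_local"] = r_loc,
                      _["inside"] = inside);
}
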