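#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Cell-cycle right-hand side. x = (x1..x4), k = 20 constants in the order
// k1s,k_gf,k14,k1d,k1,k21,k2,x2t,k32,k2d,k3s,k31,k3,k3d,k4s,k42,k34,k41,k4,k4d
static inline void cycle_rhs_c(const double *x, double gf, const double *k,
                               double *dx) {
  const double x1 = x[0], x2 = x[1], x3 = x[2], x4 = x[3];
  dx[0] = k[0] * gf / (k[1] + gf) - k[2] * x4 * x1 - k[3] * x1 / (k[4] + x1);
  dx[1] = k[5] * x1 * (k[7] - x2) / (k[6] + (k[7] - x2)) - k[8] * x2 * x3 -
          k[9] * x2;
  dx[2] = k[10] - k[8] * x2 * x3 - k[11] * x1 * x3 / (k[12] + x3) -
          k[13] * x3;
  dx[3] = k[14] + k[15] * x2 * k[16] / (k[16] + x3) -
          k[17] * x1 * x4 / (k[18] + x4) - k[19] * x4;
}

// Classical RK4 with fixed substeps of length <= hmax between the recording
// nodes `ages`; initial state (0,0,0,0). Returns a length(ages) x 4 matrix.
static void cycle_rk4_core(const double *ages, int n, double gf,
                           const double *k, double hmax, double *out) {
  double x[4] = {0.0, 0.0, 0.0, 0.0};
  double k1[4], k2[4], k3[4], k4[4], tmp[4];
  for (int j = 0; j < 4; ++j) out[0 + j * n] = 0.0;
  for (int i = 0; i < n - 1; ++i) {
    const double H = ages[i + 1] - ages[i];
    const int m = (int)std::ceil(H / hmax - 1e-12);
    const double h = H / (m > 0 ? m : 1);
    for (int s = 0; s < m; ++s) {
      cycle_rhs_c(x, gf, k, k1);
      for (int j = 0; j < 4; ++j) tmp[j] = x[j] + 0.5 * h * k1[j];
      cycle_rhs_c(tmp, gf, k, k2);
      for (int j = 0; j < 4; ++j) tmp[j] = x[j] + 0.5 * h * k2[j];
      cycle_rhs_c(tmp, gf, k, k3);
      for (int j = 0; j < 4; ++j) tmp[j] = x[j] + h * k3[j];
      cycle_rhs_c(tmp, gf, k, k4);
      for (int j = 0; j < 4; ++j)
        x[j] += h / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
    }
    for (int j = 0; j < 4; ++j) out[(i + 1) + j * n] = x[j];
  }
}

// [[Rcpp::export]]
NumericMatrix cycle_rk4_cpp(NumericVector ages, double gf, NumericVector cp,
                            double hmax) {
  const int n = ages.size();
  NumericMatrix out(n, 4);
  cycle_rk4_core(REAL(ages), n, gf, REAL(cp), hmax, REAL(out));
  return out;
}

// [[Rcpp::export]]
NumericVector cycle_rhs_cpp(NumericVector x, double gf, NumericVector cp) {
  NumericVector dx(4);
  cycle_rhs_c(REAL(x), gf, REAL(cp), REAL(dx));
  return dx;
}

// Full explicit time loop of the coupled macro/micro system.
//
// q0, p0        initial densities on the age grid (n nodes, spacing da)
// tau, mup, muq, g  age-dependent coefficients evaluated on the grid
// macro         (nu, theta, kappa, k_t, sigma1, sigma2, sigma3, gamma2, gamma3)
// cp            20 cycle constants (order above)
// refresh_tol   0 => recompute the cycle trajectory every step; > 0 =>
//               recompute only when |g_f - g_f(last recompute)| > tol
// record_every  thinning of the scalar time series
// snap_every    steps between stored (q, p) snapshots (0 = none)
//
// Returns the recorded series, snapshots, final state and the x1 profile in
// use at the final step. Stops advancing (and flags blowup_time) if N
// exceeds `nmax` or turns non-finite.
// [[Rcpp::export]]
List simulate_cpp(NumericVector q0, NumericVector p0, double da, double dt,
                  int nsteps, NumericVector tau, NumericVector mup,
                  NumericVector muq, NumericVector g, NumericVector macro,
                  NumericVector cp, double hmax, double refresh_tol,
                  int record_every, int snap_every, double nmax,
                  double clip_warn_tol) {
  const int n = q0.size();
  const double nu = macro[0], theta = macro[1], kappa = macro[2],
               kt = macro[3], s1 = macro[4], s2 = macro[5], s3 = macro[6],
               g2 = macro[7], g3 = macro[8];
  const double tk = std::pow(theta, kappa);
  const double s2g = std::pow(s2, g2), s3g = std::pow(s3, g3);

  std::vector<double> q(q0.begin(), q0.end()), p(p0.begin(), p0.end());
  std::vector<double> w(n, da);      // trapezoid weights
  w[0] = w[n - 1] = da / 2.0;
  std::vector<double> ages(n), x1(n, 0.0), chiv(n, 0.0), traj(4 * n, 0.0);
  for (int i = 0; i < n; ++i) ages[i] = i * da;
  std::vector<double> agefac(n);
  for (int i = 0; i < n; ++i)
    agefac[i] = s3g / (s3g + std::pow(ages[i], g3));

  const int nrec = nsteps / record_every + 1;
  NumericVector r_t(nrec), r_N(nrec), r_gf(nrec), r_gam(nrec), r_p0(nrec);
  int nsnap = (snap_every > 0) ? nsteps / snap_every + 1 : 0;
  NumericMatrix snap_q(nsnap > 0 ? n : 0, nsnap),
                snap_p(nsnap > 0 ? n : 0, nsnap);
  NumericVector snap_t(nsnap);

  double gf_used = -1.0;  // force first recompute
  bool have_traj = false;
  double blowup_time = NA_REAL;
  double min_before_clip = 0.0;
  int irec = 0, isnap = 0, steps_done = 0;
  std::vector<double> qn(n), pn(n);

  for (int s = 0; s <= nsteps; ++s) {
    double N = 0.0;
    for (int i = 0; i < n; ++i) N += w[i] * (q[i] + p[i]);
    const double gf = 1.0 / (1.0 + kt * N);
    const double gam = nu * tk / (tk + std::pow(N, kappa));
    double pb = 0.0;  // renewal boundary value p(0) = (2/g(0)) int tau p
    for (int i = 0; i < n; ++i) pb += w[i] * tau[i] * p[i];
    pb = 2.0 * pb / g[0];

    if (s % record_every == 0 && irec < nrec) {
      r_t[irec] = s * dt; r_N[irec] = N; r_gf[irec] = gf;
      r_gam[irec] = gam; r_p0[irec] = pb; ++irec;
    }
    if (snap_every > 0 && s % snap_every == 0 && isnap < nsnap) {
      for (int i = 0; i < n; ++i) { snap_q(i, isnap) = q[i]; snap_p(i, isnap) = p[i]; }
      snap_t[isnap] = s * dt; ++isnap;
    }
    if (!std::isfinite(N) || N > nmax) {
      blowup_time = s * dt;
      break;
    }
    if (s == nsteps) { steps_done = s; break; }

    if (!have_traj || std::fabs(gf - gf_used) > refresh_tol) {
      cycle_rk4_core(ages.data(), n, gf, REAL(cp), hmax, traj.data());
      for (int i = 0; i < n; ++i)
        x1[i] = traj[i] > 0.0 ? traj[i] : 0.0;
      for (int i = 0; i < n; ++i)
        chiv[i] = s1 * (s2g / (s2g + std::pow(x1[i], g2))) * agefac[i];
      gf_used = gf;
      have_traj = true;
    }

    for (int i = 0; i < n; ++i)
      qn[i] = q[i] + dt * (chiv[i] * p[i] - (gam + muq[i]) * q[i]);
    pn[0] = pb;
    for (int i = 1; i < n; ++i)
      pn[i] = p[i] + dt * (-(g[i] * p[i] - g[i - 1] * p[i - 1]) / da +
                           gam * q[i] -
                           (tau[i] + chiv[i] + mup[i]) * p[i]);
    for (int i = 0; i < n; ++i) {
      if (qn[i] < min_before_clip) min_before_clip = qn[i];
      if (pn[i] < min_before_clip) min_before_clip = pn[i];
      q[i] = qn[i] > 0.0 ? qn[i] : 0.0;
      p[i] = pn[i] > 0.0 ? pn[i] : 0.0;
    }
    steps_done = s + 1;
  }

  if (irec < nrec) {  // truncated by blow-up
    r_t = head(r_t, irec); r_N = head(r_N, irec); r_gf = head(r_gf, irec);
    r_gam = head(r_gam, irec); r_p0 = head(r_p0, irec);
  }
  if (nsnap > 0 && isnap < nsnap) {
    snap_q = snap_q(_, Range(0, std::max(isnap - 1, 0)));
    snap_p = snap_p(_, Range(0, std::max(isnap - 1, 0)));
    snap_t = head(snap_t, isnap);
  }
  NumericMatrix traj_out(n, 4);
  std::copy(traj.begin(), traj.end(), REAL(traj_out));

  return List::create(
      _["t"] = r_t, _["N"] = r_N, _["g_f"] = r_gf, _["gamma_N"] = r_gam,
      _["p_boundary"] = r_p0, _["q"] = NumericVector(q.begin(), q.end()),
      _["p"] = NumericVector(p.begin(), p.end()),
      _["snapshot_t"] = snap_t, _["snapshot_q"] = snap_q,
      _["snapshot_p"] = snap_p, _["cycle_states"] = traj_out,
      _["gf_used"] = gf_used, _["blowup_time"] = blowup_time,
      _["min_before_clip"] = min_before_clip,
      _["steps_done"] = steps_done,
      _["clip_warn"] = (min_before_clip < -clip_warn_tol));
}
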