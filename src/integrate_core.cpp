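#include <Rcpp.h>
using namespace Rcpp;

// C1 smoothstep Heaviside: 0 below 0, 1 above eps, 3x^2 - 2x^3 in between.
static inline double hsmooth(double tau, double eps) {
  if (tau <= 0.0) return 0.0;
  if (tau >= eps) return 1.0;
  double x = tau / eps;
  return x * x * (3.0 - 2.0 * x);
}

// Fixed-step RK4 integrator for the coupled phase/delay system
//
//   theta_i' = omega0 + (g/N) sum_j a_ij sin(theta_j(t - tau_ij(t)) - theta_i)
//   tau_ij'  = alpha_tau * H(tau_ij) * [ -(tau_ij - tau0_ij) + kappa sin(theta_j - theta_i) ]
//
// Delayed phases are read from the accumulated solution on the fixed grid by
// linear interpolation.  Within one step the lag tau_ij used for the history
// lookup is frozen at its start-of-step value (the delays move on the slow
// alpha_tau time scale, so the freeze is O(dt^2)); the delay state itself is
// advanced by the same RK4 stages as the phases.  Lags shorter than the
// current stage offset are resolved against the stage state itself, which
// makes the zero-delay limit an exact classical RK4.
//
// theta_hist: (n_hist+1) x N phases on the grid t = -n_hist*dt, ..., 0
// A_pre/A_post: adjacency before/after t_inj (set t_inj = R_PosInf for none)
// [[Rcpp::export]]
List integrate_core(NumericMatrix theta_hist,
                    NumericMatrix tau_init,
                    NumericMatrix tau_base,
                    double omega0, double g, double kappa,
                    double alpha_tau, double eps,
                    IntegerMatrix A_pre, IntegerMatrix A_post, double t_inj,
                    double dt, int n_steps, int record_stride, int tau_stride) {
  const int N = theta_hist.ncol();
  const int NN = N * N;
  const int n_hist = theta_hist.nrow() - 1;
  const int n_rows = n_hist + n_steps + 1;
  const double gN = g / static_cast<double>(N);

  // full solution grid (history + computed), row r holds t = (r - n_hist)*dt
  std::vector<double> th(static_cast<size_t>(n_rows) * N);
  for (int j = 0; j < N; ++j)
    for (int r = 0; r <= n_hist; ++r)
      th[static_cast<size_t>(j) * n_rows + r] = theta_hist(r, j);

  std::vector<double> tau(tau_init.begin(), tau_init.end());      // N x N col-major
  const std::vector<double> tau0(tau_base.begin(), tau_base.end());
  std::vector<signed char> Apre(NN), Apost(NN);
  for (int idx = 0; idx < NN; ++idx) {
    Apre[idx] = static_cast<signed char>(A_pre[idx]);
    Apost[idx] = static_cast<signed char>(A_post[idx]);
  }

  const int n_rec = n_steps / record_stride + 1 +
                    (n_steps % record_stride ? 1 : 0);
  const int n_trec = n_steps / tau_stride + 1 +
                     (n_steps % tau_stride ? 1 : 0);
  NumericVector times(n_rec), tau_times(n_trec);
  NumericMatrix theta_rec(n_rec, N), dtheta_rec(n_rec, N);
  NumericMatrix tau_rec(n_trec, NN);

  std::vector<double> th_s(N), sin_s(N), cos_s(N),
      k1t(N), k2t(N), k3t(N), k4t(N);
  std::vector<double> tau_s(NN), k1d(NN), k2d(NN), k3d(NN), k4d(NN), tauF(NN);

  int injury_step = -1;
  int irec = 0, itrec = 0;

  for (int n = 0; n <= n_steps; ++n) {
    const double t_n = n * dt;
    const int cur = n_hist + n;
    const bool injured = (t_n >= t_inj - 1e-12 * dt);
    if (injured && injury_step < 0) injury_step = n;
    const signed char* A = injured ? Apost.data() : Apre.data();

    // frozen lags for this step's history lookups
    std::copy(tau.begin(), tau.end(), tauF.begin());

    // one RK4 stage at time t_s = t_n + c*dt
    auto rhs = [&](const std::vector<double>& th_stage,
                   const std::vector<double>& tau_stage, double t_s,
                   std::vector<double>& dth_out, std::vector<double>& dtau_out) {
      for (int i = 0; i < N; ++i) {
        sin_s[i] = std::sin(th_stage[i]);
        cos_s[i] = std::cos(th_stage[i]);
      }
      const double span = t_s - t_n;
      for (int i = 0; i < N; ++i) {
        double acc = 0.0;
        const double thi = th_stage[i];
        for (int j = 0; j < N; ++j) {
          const int idx = i + N * j;
          if (!A[idx]) continue;
          const double tl = t_s - tauF[idx];
          const double* col = th.data() + static_cast<size_t>(j) * n_rows;
          double thd;
          if (tl >= t_n) {
            // lag shorter than the stage offset: use the stage state
            thd = (span > 0.0)
                      ? col[cur] + (tl - t_n) / span * (th_stage[j] - col[cur])
                      : col[cur];
          } else {
            const double x = (tl + n_hist * dt) / dt;
            const int r = static_cast<int>(x);
            if (x < 0.0)
              stop("history horizon exceeded at t=%g: lag %g s reaches beyond "
                   "the stored history (%g s); increase history_margin",
                   t_s, tauF[idx], n_hist * dt);
            const double w = x - r;
            thd = (1.0 - w) * col[r] + w * col[r + 1];
          }
          acc += std::sin(thd - thi);
        }
        dth_out[i] = omega0 + gN * acc;
      }
      for (int j = 0; j < N; ++j) {
        const double sj = sin_s[j], cj = cos_s[j];
        for (int i = 0; i < N; ++i) {
          const int idx = i + N * j;
          if (A[idx]) {
            const double tv = tau_stage[idx];
            // sin(theta_j - theta_i) via the stage sin/cos tables
            const double sd = sj * cos_s[i] - cj * sin_s[i];
            dtau_out[idx] = alpha_tau * hsmooth(tv, eps) *
                            (-(tv - tau0[idx]) + kappa * sd);
          } else {
            dtau_out[idx] = 0.0;
          }
        }
      }
    };

    // k1 at the accepted state; also serves as the recorded derivative
    for (int i = 0; i < N; ++i)
      th_s[i] = th[static_cast<size_t>(i) * n_rows + cur];
    rhs(th_s, tau, t_n, k1t, k1d);

    if ((n % record_stride == 0) || (n == n_steps)) {
      times[irec] = t_n;
      for (int i = 0; i < N; ++i) {
        theta_rec(irec, i) = th_s[i];
        dtheta_rec(irec, i) = k1t[i];
      }
      ++irec;
    }
    if ((n % tau_stride == 0) || (n == n_steps)) {
      tau_times[itrec] = t_n;
      for (int idx = 0; idx < NN; ++idx) tau_rec(itrec, idx) = tau[idx];
      ++itrec;
    }
    if (n == n_steps) break;

    std::vector<double> th0(th_s);  // accepted phases this step
    for (int i = 0; i < N; ++i) th_s[i] = th0[i] + 0.5 * dt * k1t[i];
    for (int idx = 0; idx < NN; ++idx) tau_s[idx] = tau[idx] + 0.5 * dt * k1d[idx];
    rhs(th_s, tau_s, t_n + 0.5 * dt, k2t, k2d);

    for (int i = 0; i < N; ++i) th_s[i] = th0[i] + 0.5 * dt * k2t[i];
    for (int idx = 0; idx < NN; ++idx) tau_s[idx] = tau[idx] + 0.5 * dt * k2d[idx];
    rhs(th_s, tau_s, t_n + 0.5 * dt, k3t, k3d);

    for (int i = 0; i < N; ++i) th_s[i] = th0[i] + dt * k3t[i];
    for (int idx = 0; idx < NN; ++idx) tau_s[idx] = tau[idx] + dt * k3d[idx];
    rhs(th_s, tau_s, t_n + dt, k4t, k4d);

    for (int i = 0; i < N; ++i) {
      const double v =
          th0[i] + dt / 6.0 * (k1t[i] + 2.0 * k2t[i] + 2.0 * k3t[i] + k4t[i]);
      if (!std::isfinite(v))
        stop("non-finite phase produced at step %d (t=%g s)", n + 1, t_n + dt);
      th[static_cast<size_t>(i) * n_rows + cur + 1] = v;
    }
    for (int idx = 0; idx < NN; ++idx) {
      double v =
          tau[idx] + dt / 6.0 * (k1d[idx] + 2.0 * k2d[idx] + 2.0 * k3d[idx] + k4d[idx]);
      if (!std::isfinite(v))
        stop("non-finite delay produced at step %d (t=%g s)", n + 1, t_n + dt);
      if (v < 0.0) v = 0.0;  // clamp floating-point undershoot below the H floor
      tau[idx] = v;
    }
    if ((n & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix tau_end(N, N);
  std::copy(tau.begin(), tau.end(), tau_end.begin());
  NumericVector theta_end(N);
  for (int i = 0; i < N; ++i)
    theta_end[i] = th[static_cast<size_t>(i) * n_rows + n_hist + n_steps];

  return List::create(_["times"] = times, _["theta"] = theta_rec,
                      _["dtheta"] = dtheta_rec, _["tau_times"] = tau_times,
                      _["tau"] = tau_rec, _["theta_end"] = theta_end,
                      _["tau_end"] = tau_end, _["injury_step"] = injury_step);
  }
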