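#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Two-state neuronal model + balloon-Windkessel hemodynamics, integrated
// with fixed-step RK4 at microtime resolution with zero-order hold on the
// inputs.  Hemodynamic states f, v, q are integrated in log space so they
// stay positive for any step size.
//
// Per region i (E = excitatory, I = inhibitory population):
//   dxE_i = -sigma_E xE_i + sum_{j!=i} a0 exp(A_ij + u_mod B_ij) xE_j
//           - g_IE exp(A_ii + u_mod B_ii) xI_i + C_i u_drive
//   dxI_i =  g_EI xE_i - sigma_I xI_i
// Between-region rates are log-scaled (always excitatory); the I->E gain
// is log-scaled (always inhibitory), so the diagonal entries of A/B are
// the self-inhibition parameters and their modulation.  The modulatory
// input is piecewise constant (a bin staircase), so the exponentiated
// coupling matrix is cached and refreshed only when u_mod changes.
//
// Hemodynamics (per region, driven by xE):
//   ds = xE - kappa s - gamma (f - 1)
//   d(log f) = s / f
//   d(log v) = (f - v^{1/alpha}) / (tau_i v)
//   d(log q) = (f E(f)/E0 / q - v^{1/alpha}/v) / tau_i
// with E(f) = 1 - (1 - E0)^{1/f}, and BOLD percent signal
//   y = 100 V0 (k1 (1-q) + k2 (1 - q/v) + k3 (1 - v)),
//   k1 = 7 E0, k2 = 2, k3 = 2 E0 - 0.2.

struct TwoStateModel {
  int R;
  std::vector<double> A, B, C, tau;   // A, B column-major R x R
  double sigma_E, sigma_I, g_EI, g_IE, a0;
  double kappa, gamma_, alpha, E0, V0;
  double log1mE0, ooa;

  // caches refreshed when u_mod changes
  std::vector<double> Aeff, self_gain;
  double um_cached;
  bool cache_valid;

  void refresh(double um) {
    for (int j = 0; j < R; ++j)
      for (int i = 0; i < R; ++i) {
        double w = std::exp(A[i + R * j] + um * B[i + R * j]);
        if (i == j) self_gain[i] = g_IE * w;
        else Aeff[i + R * j] = a0 * w;
      }
    um_cached = um;
    cache_valid = true;
  }

  // state layout: [xE (R), xI (R), s (R), log f (R), log v (R), log q (R)]
  void deriv(const std::vector<double>& x, double ud, double um,
             std::vector<double>& dx) {
    if (!cache_valid || um != um_cached) refresh(um);
    for (int i = 0; i < R; ++i) {
      double exc = 0.0;
      for (int j = 0; j < R; ++j)
        if (j != i) exc += Aeff[i + R * j] * x[j];
      dx[i] = -sigma_E * x[i] + exc - self_gain[i] * x[R + i] + C[i] * ud;
      dx[R + i] = g_EI * x[i] - sigma_I * x[R + i];
      double s = x[2 * R + i];
      double f = std::exp(x[3 * R + i]);
      double v = std::exp(x[4 * R + i]);
      double q = std::exp(x[5 * R + i]);
      double fv = std::exp(ooa * x[4 * R + i]);      // v^{1/alpha}
      double Ef = 1.0 - std::exp(log1mE0 / f);
      dx[2 * R + i] = x[i] - kappa * s - gamma_ * (f - 1.0);
      dx[3 * R + i] = s / f;
      dx[4 * R + i] = (f - fv) / (tau[i] * v);
      dx[5 * R + i] = (f * Ef / E0 / q - fv / v) / tau[i];
    }
  }

  double bold(const std::vector<double>& x, int i) const {
    double v = std::exp(x[4 * R + i]);
    double q = std::exp(x[5 * R + i]);
    double k1 = 7.0 * E0, k2 = 2.0, k3 = 2.0 * E0 - 0.2;
    return 100.0 * V0 *
      (k1 * (1.0 - q) + k2 * (1.0 - q / v) + k3 * (1.0 - v));
  }
};

// [[Rcpp::export(name = ".dcm_simulate_cpp")]]
NumericMatrix dcm_simulate_cpp(NumericMatrix A, NumericMatrix B,
                               NumericVector C, NumericVector tau,
                               NumericMatrix u, double dt,
                               IntegerVector n_per_run,
                               int steps_per_vol, int n_volumes,
                               List constants) {
  TwoStateModel m;
  m.R = A.nrow();
  if (A.ncol() != m.R || B.nrow() != m.R || B.ncol() != m.R ||
      C.size() != m.R || tau.size() != m.R)
    stop("parameter dimensions disagree");
  if (u.ncol() < 2) stop("u must have columns (drive, mod)");
  m.A.assign(A.begin(), A.end());
  m.B.assign(B.begin(), B.end());
  m.C.assign(C.begin(), C.end());
  m.tau.assign(tau.begin(), tau.end());
  m.sigma_E = constants["sigma_E"]; m.sigma_I = constants["sigma_I"];
  m.g_EI = constants["g_EI"]; m.g_IE = constants["g_IE"];
  m.a0 = constants["a0"];
  m.kappa = constants["kappa"]; m.gamma_ = constants["gamma"];
  m.alpha = constants["alpha"];
  m.E0 = constants["E0"]; m.V0 = constants["V0"];
  m.log1mE0 = std::log(1.0 - m.E0);
  m.ooa = 1.0 / m.alpha;
  m.Aeff.assign(m.R * m.R, 0.0);
  m.self_gain.assign(m.R, 0.0);
  m.cache_valid = false;

  for (int i = 0; i < m.R * m.R; ++i)
    if (!std::isfinite(m.A[i]) || !std::isfinite(m.B[i]))
      stop("non-finite parameters");

  int n_runs = n_per_run.size();
  NumericMatrix out(n_volumes * n_runs, m.R);
  int n_state = 6 * m.R;
  std::vector<double> x(n_state), k1(n_state), k2(n_state), k3(n_state),
    k4(n_state), xt(n_state);
  int row0 = 0, out_row = 0;
  for (int r = 0; r < n_runs; ++r) {
    std::fill(x.begin(), x.end(), 0.0);  // rest: xE=xI=s=0, f=v=q=1
    int vol = 0;
    int nr = n_per_run[r];
    if (nr < (n_volumes - 1) * steps_per_vol + 1)
      stop("inputs do not cover the scan duration of run %d", r + 1);
    for (int k = 0; k < nr; ++k) {
      if (k % steps_per_vol == 0 && vol < n_volumes) {
        for (int i = 0; i < m.R; ++i) {
          double y = m.bold(x, i);
          if (!std::isfinite(y))
            stop("integration diverged (non-finite BOLD) at run %d, volume %d",
                 r + 1, vol + 1);
          out(out_row, i) = y;
        }
        ++out_row; ++vol;
      }
      double ud = u(row0 + k, 0), um = u(row0 + k, 1);
      m.deriv(x, ud, um, k1);
      for (int i = 0; i < n_state; ++i) xt[i] = x[i] + 0.5 * dt * k1[i];
      m.deriv(xt, ud, um, k2);
      for (int i = 0; i < n_state; ++i) xt[i] = x[i] + 0.5 * dt * k2[i];
      m.deriv(xt, ud, um, k3);
      for (int i = 0; i < n_state; ++i) xt[i] = x[i] + dt * k3[i];
      m.deriv(xt, ud, um, k4);
      for (int i = 0; i < n_state; ++i) {
        x[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
        if (!std::isfinite(x[i]))
          stop("integration diverged (non-finite state) at run %d, step %d",
               r + 1, k + 1);
      }
    }
    row0 += nr;
  }
  return out;
}
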