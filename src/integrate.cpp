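// Adaptive Rosenbrock (ode23s-type, linearly implicit, L-stable) integrator for
// the lake chemostat model.  The nutrient-drawdown mode can be 10^3-10^4 times
// faster than the dilution mode, which makes explicit steppers impractical; a
// second-order Rosenbrock pair with step-doubling-free embedded error control
// handles the stiffness and the Liebig min() kink robustly.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const int MAXDIM = 5;

struct Pars {
  double mu_max, a, z_max, m_N, m_P, c_N, c_P, I_in, h_I, k_bg, k_A;
  double N_in, P_in;
  // droop extras
  double mu_inf, Qmin_N, Qmin_P, vmax_N, vmax_P;
};

// depth-averaged light limitation with self-shading
static inline double f_light(double A, const Pars &p) {
  double k = p.k_bg + p.k_A * A;
  double kz = k * p.z_max;
  double Iz = p.I_in * std::exp(-kz);
  return std::log((p.h_I + p.I_in) / (p.h_I + Iz)) / kz;
}

// fixed-quota RHS: y = (A, N, P)
static void rhs_fixed(const double *y, const Pars &p, double *dy) {
  double A = y[0], N = y[1], P = y[2];
  double fN = N / (p.m_N + N);
  double fP = P / (p.m_P + P);
  double fI = f_light(A, p);
  double f = fN < fP ? fN : fP;
  if (fI < f) f = fI;
  double mu = p.mu_max * f;
  dy[0] = (mu - p.a) * A;
  dy[1] = p.a * (p.N_in - N) - p.c_N * mu * A;
  dy[2] = p.a * (p.P_in - P) - p.c_P * mu * A;
}

// Droop RHS: y = (A, N, P, Q_N, Q_P); growth = mu_inf * min_quota * f_I
static void rhs_droop(const double *y, const Pars &p, double *dy) {
  double A = y[0], N = y[1], P = y[2];
  double QN = y[3] > p.Qmin_N ? y[3] : p.Qmin_N;
  double QP = y[4] > p.Qmin_P ? y[4] : p.Qmin_P;
  double gN = 1.0 - p.Qmin_N / QN;
  double gP = 1.0 - p.Qmin_P / QP;
  double g = gN < gP ? gN : gP;
  double mu = p.mu_inf * g * f_light(A, p);
  double vN = p.vmax_N * N / (p.m_N + N);
  double vP = p.vmax_P * P / (p.m_P + P);
  dy[0] = (mu - p.a) * A;
  dy[1] = p.a * (p.N_in - N) - vN * A;
  dy[2] = p.a * (p.P_in - P) - vP * A;
  dy[3] = vN - mu * QN;
  dy[4] = vP - mu * QP;
}

static void eval_rhs(const double *y, const Pars &p, int variant, double *dy) {
  if (variant == 0) rhs_fixed(y, p, dy); else rhs_droop(y, p, dy);
}

// finite-difference Jacobian
static void num_jac(const double *y, const Pars &p, int variant, int n,
                    double J[MAXDIM][MAXDIM]) {
  double f0[MAXDIM], f1[MAXDIM], yp[MAXDIM];
  eval_rhs(y, p, variant, f0);
  for (int j = 0; j < n; j++) {
    double h = 1e-7 * std::fabs(y[j]) + 1e-10;
    for (int i = 0; i < n; i++) yp[i] = y[i];
    yp[j] += h;
    eval_rhs(yp, p, variant, f1);
    for (int i = 0; i < n; i++) J[i][j] = (f1[i] - f0[i]) / h;
  }
}

// solve W x = b in place via Gaussian elimination with partial pivoting
static bool lin_solve(double W[MAXDIM][MAXDIM], double *b, int n) {
  int piv[MAXDIM];
  for (int i = 0; i < n; i++) piv[i] = i;
  for (int c = 0; c < n; c++) {
    int best = c;
    for (int r = c + 1; r < n; r++)
      if (std::fabs(W[r][c]) > std::fabs(W[best][c])) best = r;
    if (best != c) {
      for (int k = 0; k < n; k++) std::swap(W[c][k], W[best][k]);
      std::swap(b[c], b[best]);
    }
    if (std::fabs(W[c][c]) < 1e-300) return false;
    for (int r = c + 1; r < n; r++) {
      double m = W[r][c] / W[c][c];
      for (int k = c; k < n; k++) W[r][k] -= m * W[c][k];
      b[r] -= m * b[c];
    }
  }
  for (int r = n - 1; r >= 0; r--) {
    double s = b[r];
    for (int k = r + 1; k < n; k++) s -= W[r][k] * b[k];
    b[r] = s / W[r][r];
  }
  return true;
}

static double conv_rate(const double *y, const double *dy, int n) {
  double worst = 0.0;
  for (int i = 0; i < n; i++) {
    double r = std::fabs(dy[i]) / (std::fabs(y[i]) + 1e-6);
    if (r > worst) worst = r;
  }
  return worst;
}

// [[Rcpp::export(name = ".ode_steady_cpp")]]
List ode_steady_cpp(NumericVector y0, NumericVector par, int variant,
                    double t_max, double conv_tol, double rtol, double atol) {
  Pars p;
  p.mu_max = par[0]; p.a = par[1]; p.z_max = par[2]; p.m_N = par[3];
  p.m_P = par[4]; p.c_N = par[5]; p.c_P = par[6]; p.I_in = par[7];
  p.h_I = par[8]; p.k_bg = par[9]; p.k_A = par[10];
  p.N_in = par[11]; p.P_in = par[12];
  p.mu_inf = p.Qmin_N = p.Qmin_P = p.vmax_N = p.vmax_P = 0.0;
  if (variant == 1) {
    p.mu_inf = par[13]; p.Qmin_N = par[14]; p.Qmin_P = par[15];
    p.vmax_N = par[16]; p.vmax_P = par[17];
  }
  int n = y0.size();
  if (n > MAXDIM) stop("state dimension too large");

  const double d = 1.0 / (2.0 + std::sqrt(2.0));
  const double e32 = 6.0 + std::sqrt(2.0);
  double y[MAXDIM], ynew[MAXDIM];
  for (int i = 0; i < n; i++) y[i] = y0[i];

  double t = 0.0, h = 1e-3;
  bool converged = false;
  long nsteps = 0, nclip = 0;
  double F0[MAXDIM], F1[MAXDIM], F2[MAXDIM];
  double k1[MAXDIM], k2[MAXDIM], k3[MAXDIM], err[MAXDIM];
  double J[MAXDIM][MAXDIM], W[MAXDIM][MAXDIM];
  double rate = R_PosInf;

  eval_rhs(y, p, variant, F0);
  rate = conv_rate(y, F0, n);
  if (rate < conv_tol) converged = true;

  while (!converged && t < t_max) {
    if (h > t_max - t) h = t_max - t;
    num_jac(y, p, variant, n, J);
    bool accepted = false;
    for (int attempt = 0; attempt < 60 && !accepted; attempt++) {
      for (int i = 0; i < n; i++)
        for (int j = 0; j < n; j++)
          W[i][j] = (i == j ? 1.0 : 0.0) - h * d * J[i][j];
      double Wc[MAXDIM][MAXDIM];

      for (int i = 0; i < n; i++) { k1[i] = F0[i]; }
      std::memcpy(Wc, W, sizeof(W));
      if (!lin_solve(Wc, k1, n)) { h *= 0.5; continue; }

      for (int i = 0; i < n; i++) ynew[i] = y[i] + 0.5 * h * k1[i];
      eval_rhs(ynew, p, variant, F1);
      for (int i = 0; i < n; i++) k2[i] = F1[i] - k1[i];
      std::memcpy(Wc, W, sizeof(W));
      if (!lin_solve(Wc, k2, n)) { h *= 0.5; continue; }
      for (int i = 0; i < n; i++) k2[i] += k1[i];

      for (int i = 0; i < n; i++) ynew[i] = y[i] + h * k2[i];
      eval_rhs(ynew, p, variant, F2);
      for (int i = 0; i < n; i++)
        k3[i] = F2[i] - e32 * (k2[i] - F1[i]) - 2.0 * (k1[i] - F0[i]);
      std::memcpy(Wc, W, sizeof(W));
      if (!lin_solve(Wc, k3, n)) { h *= 0.5; continue; }

      double errnorm = 0.0;
      for (int i = 0; i < n; i++) {
        err[i] = (h / 6.0) * (k1[i] - 2.0 * k2[i] + k3[i]);
        double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
        double e = std::fabs(err[i]) / sc;
        if (e > errnorm) errnorm = e;
      }
      if (!std::isfinite(errnorm)) { h *= 0.2; continue; }
      if (errnorm <= 1.0) {
        accepted = true;
        t += h;
        for (int i = 0; i < n; i++) {
          y[i] = ynew[i];
          if (y[i] < 0.0) { y[i] = 0.0; nclip++; }       // clip negative excursions
          else if (y[i] < 1e-12) { y[i] = 0.0; nclip++; }
        }
        double fac = 0.9 * std::pow(1.0 / std::max(errnorm, 1e-10), 1.0 / 3.0);
        h *= std::min(5.0, std::max(0.2, fac));
        eval_rhs(y, p, variant, F0);
        for (int i = 0; i < n; i++)
          if (!std::isfinite(F0[i]))
            stop("numerical failure: non-finite derivative in state %d", i + 1);
        rate = conv_rate(y, F0, n);
        if (rate < conv_tol) converged = true;
      } else {
        double fac = 0.9 * std::pow(1.0 / errnorm, 1.0 / 3.0);
        h *= std::max(0.1, fac);
      }
    }
    if (!accepted) stop("numerical failure: integrator step rejected repeatedly");
    if (++nsteps > 2000000L) stop("numerical failure: step budget exhausted");
  }

  NumericVector out(n);
  for (int i = 0; i < n; i++) out[i] = y[i];
  return List::create(_["state"] = out, _["t_end"] = t,
                      _["converged"] = converged, _["rate"] = rate,
                      _["n_steps"] = (double)nsteps, _["n_clip"] = (double)nclip);
}
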