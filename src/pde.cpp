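#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Conservative finite-volume stepper for the electrotaxis
// reaction-advection-diffusion model in normalised density u = rho / K:
//
//   du/dt = div(D u grad u) - div(u * chi(u) * E) + r u (1 - u),
//   chi(u) = alpha * s_eff_plus(t) * (delta + (1 - delta) u),
//   E(x, t) = (mx(t) * Ex(x), my(t) * Ey(x)),
//
// on a uniform cell-centred grid. The integer mask marks the computational
// domain (the region containing the monolayer): faces touching a
// masked-out cell carry zero flux, which imposes no-flux conditions on the
// mask boundary; masked-out cells are inert. Operator splitting per step:
// explicit first-order upwind advection (CFL-limited), backward-Euler
// diffusion with lagged face coefficient D * ubar (an M-matrix tridiagonal
// solve per grid line, unconditionally stable, conservative), and an exact
// logistic update for the reaction. 1D runs are the ny == 1 case of the
// same code path, so y-uniform 2D problems reduce to the 1D solver except
// for roundoff.

static inline double lin_interp(const NumericVector &t, const NumericVector &v,
                                double x) {
  int n = t.size();
  if (x <= t[0]) return v[0];
  if (x >= t[n - 1]) return v[n - 1];
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (t[mid] <= x) lo = mid; else hi = mid;
  }
  double w = (x - t[lo]) / (t[hi] - t[lo]);
  return v[lo] + w * (v[hi] - v[lo]);
}

static inline double window_max_abs(const NumericVector &t,
                                    const NumericVector &v, double t0,
                                    double t1) {
  double m = std::max(std::fabs(lin_interp(t, v, t0)),
                      std::fabs(lin_interp(t, v, t1)));
  for (int i = 0; i < t.size(); ++i)
    if (t[i] > t0 && t[i] < t1) m = std::max(m, std::fabs(v[i]));
  return m;
}

// Thomas solve of the implicit diffusion system along one grid line of
// length n. d holds the n+1 face diffusivities (d[0] = d[n] = 0 enforces
// no-flux; interior zero entries decouple masked-out cells).
static void implicit_diffusion_line(std::vector<double> &u,
                                    const std::vector<double> &d, double lam,
                                    int n, std::vector<double> &cp,
                                    std::vector<double> &dp) {
  if (n == 1) return;
  double b0 = 1.0 + lam * (d[0] + d[1]);
  cp[0] = (-lam * d[1]) / b0;
  dp[0] = u[0] / b0;
  for (int i = 1; i < n; ++i) {
    double a = -lam * d[i];
    double b = 1.0 + lam * (d[i] + d[i + 1]);
    double c = -lam * d[i + 1];
    double m = b - a * cp[i - 1];
    cp[i] = c / m;
    dp[i] = (u[i] - a * dp[i - 1]) / m;
  }
  u[n - 1] = dp[n - 1];
  for (int i = n - 2; i >= 0; --i) u[i] = dp[i] - cp[i] * u[i + 1];
}

// [[Rcpp::export]]
List solve_rad_cpp(NumericMatrix u0, IntegerMatrix mask, double h, double D,
                   double alpha, double delta, double r, NumericVector sig_t,
                   NumericVector sig_v, NumericVector mod_t, NumericVector mx,
                   NumericVector my, NumericMatrix Ex, NumericMatrix Ey,
                   NumericVector out_times, double dt_max, double cfl) {
  const int nx = u0.nrow(), ny = u0.ncol();
  const int n_out = out_times.size();
  NumericMatrix u(clone(u0));
  for (int i = 0; i < nx * ny; ++i)
    if (!mask[i]) u[i] = 0.0;

  double ex_max = 0.0, ey_max = 0.0;
  for (int k = 0; k < nx * ny; ++k) {
    if (!mask[k]) continue;
    ex_max = std::max(ex_max, std::fabs(Ex[k]));
    ey_max = std::max(ey_max, std::fabs(Ey[k]));
  }

  int nmax = std::max(nx, ny);
  std::vector<double> line(nmax), face(nmax + 1), cp(nmax), dp(nmax),
      flux(nmax + 1);

  List out(n_out);
  out[0] = clone(u);

  for (int k = 0; k + 1 < n_out; ++k) {
    double t0 = out_times[k], t1 = out_times[k + 1];

    // conservative CFL bound for the explicit advection over this interval
    double s_max = window_max_abs(sig_t, sig_v, t0, t1);
    double mx_max = window_max_abs(mod_t, mx, t0, t1);
    double my_max = window_max_abs(mod_t, my, t0, t1);
    double u_max = 1.0;
    for (int i = 0; i < nx * ny; ++i) u_max = std::max(u_max, u[i]);
    double chi_max = alpha * s_max * (delta + (1.0 - delta) * u_max);
    double a_bound =
        std::max(chi_max * mx_max * ex_max, chi_max * my_max * ey_max);
    double dt_t = dt_max;
    if (a_bound > 0.0) dt_t = std::min(dt_t, cfl * h / a_bound);
    int n_sub = (int)std::ceil((t1 - t0) / dt_t - 1e-12);
    if (n_sub < 1) n_sub = 1;
    double dt = (t1 - t0) / n_sub;
    double lam = dt / (h * h);

    for (int j = 0; j < n_sub; ++j) {
      double t = t0 + j * dt;
      double s = lin_interp(sig_t, sig_v, t);
      if (s < 0.0) s = 0.0;
      double mxv = lin_interp(mod_t, mx, t);
      double myv = lin_interp(mod_t, my, t);

      // ---- x sweep: explicit upwind advection, implicit diffusion ----
      for (int jy = 0; jy < ny; ++jy) {
        for (int i = 0; i < nx; ++i) line[i] = u(i, jy);
        if (nx > 1) {
          for (int i = 0; i <= nx; ++i) flux[i] = 0.0;
          if (alpha > 0.0 && s > 0.0 && mxv != 0.0) {
            for (int i = 1; i < nx; ++i) {
              if (!mask(i - 1, jy) || !mask(i, jy)) continue;
              double ubar = 0.5 * (line[i - 1] + line[i]);
              double ef = 0.5 * (Ex(i - 1, jy) + Ex(i, jy));
              double a =
                  alpha * s * (delta + (1.0 - delta) * ubar) * mxv * ef;
              flux[i] = (a > 0.0) ? a * line[i - 1] : a * line[i];
            }
          }
          for (int i = 0; i < nx; ++i)
            line[i] -= dt / h * (flux[i + 1] - flux[i]);
          face[0] = 0.0;
          face[nx] = 0.0;
          for (int i = 1; i < nx; ++i)
            face[i] = (mask(i - 1, jy) && mask(i, jy))
                          ? D * 0.5 * (line[i - 1] + line[i])
                          : 0.0;
          implicit_diffusion_line(line, face, lam, nx, cp, dp);
        }
        for (int i = 0; i < nx; ++i) u(i, jy) = line[i];
      }

      // ---- y sweep ----
      if (ny > 1) {
        for (int ix = 0; ix < nx; ++ix) {
          for (int jy2 = 0; jy2 < ny; ++jy2) line[jy2] = u(ix, jy2);
          for (int jy2 = 0; jy2 <= ny; ++jy2) flux[jy2] = 0.0;
          if (alpha > 0.0 && s > 0.0 && myv != 0.0) {
            for (int jy2 = 1; jy2 < ny; ++jy2) {
              if (!mask(ix, jy2 - 1) || !mask(ix, jy2)) continue;
              double ubar = 0.5 * (line[jy2 - 1] + line[jy2]);
              double ef = 0.5 * (Ey(ix, jy2 - 1) + Ey(ix, jy2));
              double a =
                  alpha * s * (delta + (1.0 - delta) * ubar) * myv * ef;
              flux[jy2] = (a > 0.0) ? a * line[jy2 - 1] : a * line[jy2];
            }
          }
          for (int jy2 = 0; jy2 < ny; ++jy2)
            line[jy2] -= dt / h * (flux[jy2 + 1] - flux[jy2]);
          face[0] = 0.0;
          face[ny] = 0.0;
          for (int jy2 = 1; jy2 < ny; ++jy2)
            face[jy2] = (mask(ix, jy2 - 1) && mask(ix, jy2))
                            ? D * 0.5 * (line[jy2 - 1] + line[jy2])
                            : 0.0;
          implicit_diffusion_line(line, face, lam, ny, cp, dp);
          for (int jy2 = 0; jy2 < ny; ++jy2) u(ix, jy2) = line[jy2];
        }
      }

      // ---- reaction: exact logistic update ----
      if (r > 0.0) {
        double er = std::exp(r * dt);
        for (int i = 0; i < nx * ny; ++i) {
          if (!mask[i]) continue;
          u[i] = u[i] * er / (1.0 + u[i] * (er - 1.0));
        }
      }

      // guard positivity: roundoff-scale negatives are clipped, real
      // violations abort
      for (int i = 0; i < nx * ny; ++i) {
        if (u[i] < 0.0) {
          if (u[i] < -1e-9) stop("positivity failure in finite-volume update");
          u[i] = 0.0;
        }
      }
    }
    out[k + 1] = clone(u);
  }
  return out;
}
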