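#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <set>
#include <algorithm>
using namespace Rcpp;

// Gaussian-modulated chemotactic force kernel: exp(-u^2/2) * u / (1 + u^2).
// Odd in u, and exactly so in IEEE arithmetic (u^2, exp and the quotient are
// sign-symmetric), which the mirror-paired summations below rely on.
static inline double force_term(double u) {
  return std::exp(-0.5 * u * u) * (u / (1.0 + u * u));
}

// Simpson weights (h/3)*(1,4,2,...,2,4,1); n must be odd (even interval count)
static std::vector<double> simpson_w(int n, double h) {
  std::vector<double> w(n);
  for (int i = 0; i < n; ++i) w[i] = (i % 2 == 1) ? 4.0 : 2.0;
  w[0] = 1.0;
  w[n - 1] = 1.0;
  const double h3 = h / 3.0;
  for (int i = 0; i < n; ++i) w[i] *= h3;
  return w;
}

// Node offsets from the bead computed by index arithmetic, u_i = (i-j0)*h - r
// with j0 the nearest node and r the sub-grid remainder. When the bead sits
// exactly on node j0 (r == 0) the offsets are exactly antisymmetric about j0,
// so a mirror-symmetric field produces an exactly zero force.
static int node_offsets(int n, double h, double xp, std::vector<double>& u) {
  long long j = (long long)std::llround(xp / h);
  if (j < 0) j = 0;
  if (j > n - 1) j = n - 1;
  int j0 = (int)j;
  double r = xp - (double)j0 * h;
  u.resize(n);
  for (int i = 0; i < n; ++i) u[i] = (double)(i - j0) * h - r;
  return j0;
}

static double speed_1d(const double* a, int n, double h, double A0,
                       const std::vector<double>& w, const std::vector<double>& u,
                       int j0) {
  double acc = w[j0] * force_term(u[j0]) * a[j0];
  int kmax = std::max(j0, n - 1 - j0);
  for (int k = 1; k <= kmax; ++k) {
    double s = 0.0;
    int il = j0 - k, ir = j0 + k;
    if (il >= 0) s += w[il] * force_term(u[il]) * a[il];
    if (ir <= n - 1) s += w[ir] * force_term(u[ir]) * a[ir];
    acc += s;
  }
  return A0 * acc;
}

// [[Rcpp::export]]
NumericVector cpp_removal_rate(NumericVector a, double h, double xp, double c) {
  int n = a.size();
  std::vector<double> u;
  node_offsets(n, h, xp, u);
  NumericVector out(n);
  const double inv2c2 = 1.0 / (2.0 * c * c);
  for (int i = 0; i < n; ++i) out[i] = std::exp(-u[i] * u[i] * inv2c2) * a[i];
  return out;
}

// [[Rcpp::export]]
double cpp_bead_speed(NumericVector a, double h, double xp, double A0) {
  int n = a.size();
  std::vector<double> u;
  int j0 = node_offsets(n, h, xp, u);
  std::vector<double> w = simpson_w(n, h);
  return speed_1d(REAL(a), n, h, A0, w, u, j0);
}

// Full 1D Euler loop. mode: 0 = base (removal only), 1 = rebinding from a
// well-mixed buffer, 2 = saturating surface diffusion. Speeds are evaluated
// on the pre-update field; field and bead advance simultaneously.
// [[Rcpp::export]]
List cpp_simulate_1d(NumericVector a0, double h, double xp0, double A0, double c,
                     double dtau, int nsteps, int mode,
                     NumericVector d, double ab0, double kr, double kc,
                     double kappa, IntegerVector snap_steps, double stop_margin) {
  int n = a0.size();
  if (n < 3 || n % 2 == 0) stop("grid must have an odd node count (even intervals)");
  if (c <= 0) stop("c must be positive");
  const double L = (double)(n - 1) * h;
  std::vector<double> a(a0.begin(), a0.end());
  std::vector<double> w = simpson_w(n, h);
  std::vector<double> u;
  const double inv2c2 = 1.0 / (2.0 * c * c);
  const double h2 = h * h;

  std::vector<double> lap_d;
  double dmax = 0.0;
  if (mode == 1 || mode == 2) {
    if (d.size() != n) stop("binding-site field must share the ParA grid");
    for (int i = 0; i < n; ++i) dmax = std::max(dmax, d[i]);
  }
  if (mode == 2) {
    if (kappa < 0) stop("kappa must be non-negative");
    if (kappa * dmax * dtau / h2 > 0.5)
      stop("diffusion step unstable: kappa*max(d)*dtau/dx^2 = %f > 0.5; reduce dtau or kappa",
           kappa * dmax * dtau / h2);
    lap_d.resize(n);
    for (int i = 0; i < n; ++i) {
      double dl = (i == 0) ? d[1] : d[i - 1];       // zero-flux mirror ghosts
      double dr = (i == n - 1) ? d[n - 2] : d[i + 1];
      lap_d[i] = (dl - 2.0 * d[i] + dr) / h2;
    }
  }

  std::set<int> snaps(snap_steps.begin(), snap_steps.end());
  List snapshots;
  std::vector<double> snap_tau;

  std::vector<double> rec_tau, rec_xp, rec_v, rec_ab;
  rec_tau.reserve(nsteps + 1);
  rec_xp.reserve(nsteps + 1);
  rec_v.reserve(nsteps + 1);
  if (mode == 1) rec_ab.reserve(nsteps + 1);

  double xp = xp0, ab = ab0;
  long long n_clamped = 0;
  bool boundary_hit = false;

  if (snaps.count(0)) {
    snapshots.push_back(NumericVector(a.begin(), a.end()));
    snap_tau.push_back(0.0);
  }

  for (int k = 0; k <= nsteps; ++k) {
    int j0 = node_offsets(n, h, xp, u);
    double v = speed_1d(a.data(), n, h, A0, w, u, j0);
    rec_tau.push_back((double)k * dtau);
    rec_xp.push_back(xp);
    rec_v.push_back(v);
    if (mode == 1) rec_ab.push_back(ab);
    if (k == nsteps) break;

    if (mode == 0) {
      for (int i = 0; i < n; ++i) {
        double rem = std::exp(-u[i] * u[i] * inv2c2) * a[i];
        double an = a[i] - dtau * rem;
        if (an < 0.0) { an = 0.0; ++n_clamped; }
        a[i] = an;
      }
    } else if (mode == 1) {
      double s_rem = 0.0, s_reb = 0.0;
      // removal + rebinding; buffer balanced with the same Simpson sums so the
      // discrete mass integral(a) + L*a_b is conserved exactly
      std::vector<double> da(n);
      for (int i = 0; i < n; ++i) {
        double rem = std::exp(-u[i] * u[i] * inv2c2) * a[i];
        double reb = ab * (d[i] - a[i]) * (kr + kc * a[i]);
        s_rem += w[i] * rem;
        s_reb += w[i] * reb;
        da[i] = dtau * (reb - rem);
      }
      for (int i = 0; i < n; ++i) {
        double an = a[i] + da[i];
        if (an < 0.0) { an = 0.0; ++n_clamped; }
        if (an > d[i] + 1e-9) {
          double sugg = 1.0 / (ab * (kr + kc * dmax) + 1e-300);
          stop("dtau too large for rebinding: a exceeds d; use dtau below %g", sugg);
        }
        a[i] = an;
      }
      ab += dtau * (s_rem - s_reb) / L;
    } else {
      std::vector<double> aprev(a);
      for (int i = 0; i < n; ++i) {
        double al = (i == 0) ? aprev[1] : aprev[i - 1];
        double ar = (i == n - 1) ? aprev[n - 2] : aprev[i + 1];
        double lap_a = (al - 2.0 * aprev[i] + ar) / h2;
        double rem = std::exp(-u[i] * u[i] * inv2c2) * aprev[i];
        double an = aprev[i] + dtau * (kappa * (d[i] * lap_a - aprev[i] * lap_d[i]) - rem);
        if (an < 0.0) { an = 0.0; ++n_clamped; }
        a[i] = an;
      }
    }

    xp += dtau * v;
    if (xp < 0.0) xp = 0.0;
    if (xp > L) xp = L;

    if (snaps.count(k + 1)) {
      snapshots.push_back(NumericVector(a.begin(), a.end()));
      snap_tau.push_back((double)(k + 1) * dtau);
    }
    if (stop_margin > 0.0 && (xp < stop_margin || xp > L - stop_margin)) {
      boundary_hit = true;
      int j1 = node_offsets(n, h, xp, u);
      double vf = speed_1d(a.data(), n, h, A0, w, u, j1);
      rec_tau.push_back((double)(k + 1) * dtau);
      rec_xp.push_back(xp);
      rec_v.push_back(vf);
      if (mode == 1) rec_ab.push_back(ab);
      break;
    }
  }

  List out = List::create(
    _["tau"] = NumericVector(rec_tau.begin(), rec_tau.end()),
    _["x_p"] = NumericVector(rec_xp.begin(), rec_xp.end()),
    _["v"] = NumericVector(rec_v.begin(), rec_v.end()),
    _["a_b"] = (mode == 1) ? NumericVector(rec_ab.begin(), rec_ab.end()) : NumericVector(0),
    _["a_final"] = NumericVector(a.begin(), a.end()),
    _["snapshots"] = snapshots,
    _["snapshot_tau"] = NumericVector(snap_tau.begin(), snap_tau.end()),
    _["n_clamped"] = (double)n_clamped,
    _["boundary_hit"] = boundary_hit);
  return out;
}

// 2D vector force by tensor-product Simpson quadrature. v_x sums mirror pairs
// in x (odd direction), v_y mirror pairs in y, for exact symmetry nulls.
static void velocity_2d(const double* a, int nx, int ny, double h,
                        double xp, double yp, double A0,
                        const std::vector<double>& wx, const std::vector<double>& wy,
                        double* vout) {
  std::vector<double> ux, uy;
  int i0 = node_offsets(nx, h, xp, ux);
  int j0 = node_offsets(ny, h, yp, uy);
  std::vector<double> ex(nx), ey(ny);
  for (int i = 0; i < nx; ++i) ex[i] = std::exp(-0.5 * ux[i] * ux[i]);
  for (int j = 0; j < ny; ++j) ey[j] = std::exp(-0.5 * uy[j] * uy[j]);

  // a is nx x ny, column-major (R matrix: row index i <-> x, column j <-> y)
  double vx = 0.0;
  for (int j = 0; j < ny; ++j) {
    const double* acol = a + (size_t)j * nx;
    double gy = wy[j] * ey[j];
    double uy2 = uy[j] * uy[j];
    double row = 0.0;
    {
      double q = ux[i0] / (1.0 + ux[i0] * ux[i0] + uy2);
      row = wx[i0] * ex[i0] * q * acol[i0];
    }
    int kmax = std::max(i0, nx - 1 - i0);
    for (int k = 1; k <= kmax; ++k) {
      double s = 0.0;
      int il = i0 - k, ir = i0 + k;
      if (il >= 0) {
        double q = ux[il] / (1.0 + ux[il] * ux[il] + uy2);
        s += wx[il] * ex[il] * q * acol[il];
      }
      if (ir <= nx - 1) {
        double q = ux[ir] / (1.0 + ux[ir] * ux[ir] + uy2);
        s += wx[ir] * ex[ir] * q * acol[ir];
      }
      row += s;
    }
    vx += gy * row;
  }

  double vy = 0.0;
  for (int i = 0; i < nx; ++i) {
    double gx = wx[i] * ex[i];
    double ux2 = ux[i] * ux[i];
    double col = 0.0;
    {
      double q = uy[j0] / (1.0 + ux2 + uy[j0] * uy[j0]);
      col = wy[j0] * ey[j0] * q * a[(size_t)j0 * nx + i];
    }
    int kmax = std::max(j0, ny - 1 - j0);
    for (int k = 1; k <= kmax; ++k) {
      double s = 0.0;
      int jl = j0 - k, jr = j0 + k;
      if (jl >= 0) {
        double q = uy[jl] / (1.0 + ux2 + uy[jl] * uy[jl]);
        s += wy[jl] * ey[jl] * q * a[(size_t)jl * nx + i];
      }
      if (jr <= ny - 1) {
        double q = uy[jr] / (1.0 + ux2 + uy[jr] * uy[jr]);
        s += wy[jr] * ey[jr] * q * a[(size_t)jr * nx + i];
      }
      col += s;
    }
    vy += gx * col;
  }

  vout[0] = A0 * vx;
  vout[1] = A0 * vy;
}

// [[Rcpp::export]]
NumericVector cpp_velocity_2d(NumericMatrix a, double h, double xp, double yp,
                              double A0) {
  int nx = a.nrow(), ny = a.ncol();
  if (nx % 2 == 0 || ny % 2 == 0) stop("2D grid must have odd node counts");
  std::vector<double> wx = simpson_w(nx, h), wy = simpson_w(ny, h);
  NumericVector v(2);
  velocity_2d(REAL(a), nx, ny, h, xp, yp, A0, wx, wy, REAL(v));
  return v;
}

// [[Rcpp::export]]
List cpp_simulate_2d(NumericMatrix a0, double h, double xp0, double yp0,
                     double A0, double c, double dtau, int nsteps, int mode,
                     NumericMatrix d, double ab0, double kr, double kc,
                     IntegerVector snap_steps) {
  int nx = a0.nrow(), ny = a0.ncol();
  if (nx < 3 || nx % 2 == 0 || ny < 3 || ny % 2 == 0)
    stop("2D grid must have odd node counts (even intervals)");
  if (c <= 0) stop("c must be positive");
  const double Lx = (double)(nx - 1) * h, Ly = (double)(ny - 1) * h;
  std::vector<double> a(a0.begin(), a0.end());
  std::vector<double> wx = simpson_w(nx, h), wy = simpson_w(ny, h);
  const double inv2c2 = 1.0 / (2.0 * c * c);

  double dmax = 0.0;
  if (mode == 1) {
    if (d.nrow() != nx || d.ncol() != ny) stop("binding-site field must share the grid");
    for (int i = 0; i < nx * ny; ++i) dmax = std::max(dmax, d[i]);
  }

  std::set<int> snaps(snap_steps.begin(), snap_steps.end());
  List snapshots;
  std::vector<double> snap_tau;

  std::vector<double> rec_tau, rec_xp, rec_yp, rec_vx, rec_vy, rec_ab;
  double xp = xp0, yp = yp0, ab = ab0;
  long long n_clamped = 0;
  std::vector<double> ux, uy;
  double v[2];

  if (snaps.count(0)) {
    NumericMatrix s(nx, ny);
    std::copy(a.begin(), a.end(), s.begin());
    snapshots.push_back(s);
    snap_tau.push_back(0.0);
  }

  for (int k = 0; k <= nsteps; ++k) {
    velocity_2d(a.data(), nx, ny, h, xp, yp, A0, wx, wy, v);
    rec_tau.push_back((double)k * dtau);
    rec_xp.push_back(xp);
    rec_yp.push_back(yp);
    rec_vx.push_back(v[0]);
    rec_vy.push_back(v[1]);
    if (mode == 1) rec_ab.push_back(ab);
    if (k == nsteps) break;

    node_offsets(nx, h, xp, ux);
    node_offsets(ny, h, yp, uy);
    std::vector<double> gx(nx), gy(ny);
    for (int i = 0; i < nx; ++i) gx[i] = std::exp(-ux[i] * ux[i] * inv2c2);
    for (int j = 0; j < ny; ++j) gy[j] = std::exp(-uy[j] * uy[j] * inv2c2);

    if (mode == 0) {
      for (int j = 0; j < ny; ++j) {
        double* acol = a.data() + (size_t)j * nx;
        for (int i = 0; i < nx; ++i) {
          double an = acol[i] - dtau * gx[i] * gy[j] * acol[i];
          if (an < 0.0) { an = 0.0; ++n_clamped; }
          acol[i] = an;
        }
      }
    } else {
      double s_rem = 0.0, s_reb = 0.0;
      const double* dd = REAL(d);
      std::vector<double> da((size_t)nx * ny);
      for (int j = 0; j < ny; ++j) {
        const double* acol = a.data() + (size_t)j * nx;
        const double* dcol = dd + (size_t)j * nx;
        double* dacol = da.data() + (size_t)j * nx;
        for (int i = 0; i < nx; ++i) {
          double rem = gx[i] * gy[j] * acol[i];
          double reb = ab * (dcol[i] - acol[i]) * (kr + kc * acol[i]);
          s_rem += wx[i] * wy[j] * rem;
          s_reb += wx[i] * wy[j] * reb;
          dacol[i] = dtau * (reb - rem);
        }
      }
      for (int j = 0; j < ny; ++j) {
        double* acol = a.data() + (size_t)j * nx;
        const double* dcol = dd + (size_t)j * nx;
        double* dacol = da.data() + (size_t)j * nx;
        for (int i = 0; i < nx; ++i) {
          double an = acol[i] + dacol[i];
          if (an < 0.0) { an = 0.0; ++n_clamped; }
          if (an > dcol[i] + 1e-9) {
            double sugg = 1.0 / (ab * (kr + kc * dmax) + 1e-300);
            stop("dtau too large for rebinding: a exceeds d; use dtau below %g", sugg);
          }
          acol[i] = an;
        }
      }
      ab += dtau * (s_rem - s_reb) / (Lx * Ly);
    }

    xp += dtau * v[0];
    yp += dtau * v[1];
    if (xp < 0.0) xp = 0.0;
    if (xp > Lx) xp = Lx;
    if (yp < 0.0) yp = 0.0;
    if (yp > Ly) yp = Ly;

    if (snaps.count(k + 1)) {
      NumericMatrix s(nx, ny);
      std::copy(a.begin(), a.end(), s.begin());
      snapshots.push_back(s);
      snap_tau.push_back((double)(k + 1) * dtau);
    }
  }

  NumericMatrix afin(nx, ny);
  std::copy(a.begin(), a.end(), afin.begin());
  return List::create(
    _["tau"] = NumericVector(rec_tau.begin(), rec_tau.end()),
    _["x_p"] = NumericVector(rec_xp.begin(), rec_xp.end()),
    _["y_p"] = NumericVector(rec_yp.begin(), rec_yp.end()),
    _["v_x"] = NumericVector(rec_vx.begin(), rec_vx.end()),
    _["v_y"] = NumericVector(rec_vy.begin(), rec_vy.end()),
    _["a_b"] = (mode == 1) ? NumericVector(rec_ab.begin(), rec_ab.end()) : NumericVector(0),
    _["a_final"] = afin,
    _["snapshots"] = snapshots,
    _["snapshot_tau"] = NumericVector(snap_tau.begin(), snap_tau.end()),
    _["n_clamped"] = (double)n_clamped);
}
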