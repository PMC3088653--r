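// Core numerics for the membrane contour model: discrete geometry,
// variational forces, conservative protein transport, explicit Euler
// stepping.  All forces are exact gradients of the discrete free energy
// implemented in R/forces.R (same functional), so that analytic forces and
// central-difference variations of the energy agree to rounding error.
//
// Conventions (fixed package-wide):
//   * counterclockwise closed contours; outward unit normal;
//   * curvature H of a ccw circle of radius R is -1/R, so outward
//     protrusions have H < 0 (matching convex proteins, Hbar < 0);
//   * flat geometry: periodic Monge height field h(x), H = h_xx
//     (linearised curvature), forces per unit projected area (w * dx).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline int ip(int i, int N) { return (i + 1 == N) ? 0 : i + 1; }
static inline int im(int i, int N) { return (i == 0) ? N - 1 : i - 1; }

struct Par {
  double xi, D, phi_bar, n_s, kappa, Hbar, lam, gamma, J_bind, K_area,
      R0, Lambda, lam_nl, A_actin, alpha_adh, w, temperature, u0, lg2;
};

static Par par_from_list(const List& p) {
  Par q;
  q.xi = as<double>(p["xi"]);
  q.D = as<double>(p["D"]);
  q.phi_bar = as<double>(p["phi_bar"]);
  q.n_s = as<double>(p["n_s"]);
  q.kappa = as<double>(p["kappa"]);
  q.Hbar = as<double>(p["Hbar"]);
  q.lam = as<double>(p["lam"]);
  q.gamma = as<double>(p["gamma"]);
  q.J_bind = as<double>(p["J_bind"]);
  q.K_area = as<double>(p["K_area"]);
  q.R0 = as<double>(p["R0"]);
  q.Lambda = as<double>(p["Lambda"]);
  q.lam_nl = as<double>(p["lam_nl"]);
  q.A_actin = as<double>(p["A_actin"]);
  q.alpha_adh = as<double>(p["alpha_adh"]);
  q.w = as<double>(p["w"]);
  q.temperature = as<double>(p["temperature"]);
  q.u0 = as<double>(p["u0"]);
  q.lg2 = 1.0 / q.n_s;  // protein-scale area sets the aggregation
                        // gradient length
  return q;
}

// Effective (nonlinearly hardening) membrane tension, Eq.-8-type form.
static inline double lam_eff_of(double L, double L0, const Par& p) {
  if (p.lam_nl == 0.0) return p.lam;
  double u = (L - L0) / L0;
  return p.lam * (1.0 + p.lam_nl * expm1(u / p.u0));
}

// ---------------------------------------------------------------------------
// Flat (periodic Monge) geometry
// ---------------------------------------------------------------------------

struct FlatGeom {
  std::vector<double> elen, slope, ds, H;
  double L;
  void compute(const std::vector<double>& h, double dx) {
    int N = (int)h.size();
    elen.resize(N); slope.resize(N); ds.resize(N); H.resize(N);
    L = 0.0;
    double dx2 = dx * dx;
    for (int e = 0; e < N; ++e) {
      double dh = h[ip(e, N)] - h[e];
      elen[e] = std::sqrt(dx2 + dh * dh);
      slope[e] = dh / elen[e];
      L += elen[e];
    }
    for (int i = 0; i < N; ++i) {
      ds[i] = 0.5 * (elen[im(i, N)] + elen[i]);
      H[i] = (h[ip(i, N)] - 2.0 * h[i] + h[im(i, N)]) / dx2;
    }
  }
};

struct FlatForces {
  std::vector<double> f_curv, f_tension, f_tension_adh, f_spring, f_agg,
      f_actin, f_total, vn;
  double lamL, M, phimean;
  void compute(const std::vector<double>& h, const std::vector<double>& phi,
               double dx, const Par& p, double L0, const FlatGeom& g) {
    int N = (int)h.size();
    f_curv.assign(N, 0.0); f_tension.assign(N, 0.0);
    f_tension_adh.assign(N, 0.0); f_spring.assign(N, 0.0);
    f_agg.assign(N, 0.0); f_actin.assign(N, 0.0); f_total.assign(N, 0.0);
    vn.assign(N, 0.0);
    double dx2 = dx * dx;
    lamL = lam_eff_of(g.L, L0, p);
    M = 0.0;
    for (int i = 0; i < N; ++i) M += phi[i] * g.ds[i];
    phimean = M / g.L;
    std::vector<double> c(N), c2(N), ge(N);
    for (int i = 0; i < N; ++i) {
      c[i] = g.H[i] - p.Hbar * phi[i];
      c2[i] = c[i] * c[i];
    }
    for (int e = 0; e < N; ++e) {
      double dphi = (phi[ip(e, N)] - phi[e]) / g.elen[e];
      ge[e] = dphi * dphi;
    }
    double aggpre = p.J_bind * p.n_s * p.lg2 / (2.0 * dx);
    for (int j = 0; j < N; ++j) {
      int jm_ = im(j, N), jp_ = ip(j, N);
      double sm = g.slope[jm_], sp = g.slope[j];
      // curvature-mismatch force: exact gradient of
      // (w kappa/2) sum ds_i (H_i - Hbar phi_i)^2 with H linearised
      double sten = (g.ds[jm_] * c[jm_] - 2.0 * g.ds[j] * c[j] +
                     g.ds[jp_] * c[jp_]) / dx2;
      double metric = 0.5 * ((c2[jm_] + c2[j]) * 0.5 * sm -
                             (c2[j] + c2[jp_]) * 0.5 * sp);
      f_curv[j] = -(p.kappa / dx) * (sten + metric);
      // tension (bare, nonlinear in L) + adhesion reduction
      double ft = -(lamL / dx) * (sm - sp);
      double fa = (p.alpha_adh / dx) *
                  (0.5 * (phi[jm_] + phi[j]) * sm -
                   0.5 * (phi[j] + phi[jp_]) * sp);
      f_tension_adh[j] = fa;
      f_tension[j] = ft + fa;
      f_spring[j] = -p.gamma * h[j];
      f_agg[j] = aggpre * (ge[jm_] * sm - ge[j] * sp);
      f_actin[j] = p.A_actin * (phi[j] - phimean);
      f_total[j] = f_curv[j] + f_tension[j] + f_spring[j] + f_agg[j] +
                   f_actin[j];
      vn[j] = f_total[j] / p.xi;
    }
  }
};

// ---------------------------------------------------------------------------
// Round (closed polyline) geometry
// ---------------------------------------------------------------------------

struct RoundGeom {
  std::vector<double> elen, ex, ey, ds, H, nx, ny, tx, ty;
  double L, area;
  void compute(const std::vector<double>& x, const std::vector<double>& y) {
    int N = (int)x.size();
    elen.resize(N); ex.resize(N); ey.resize(N); ds.resize(N); H.resize(N);
    nx.resize(N); ny.resize(N); tx.resize(N); ty.resize(N);
    L = 0.0; area = 0.0;
    for (int e = 0; e < N; ++e) {
      int f = ip(e, N);
      ex[e] = x[f] - x[e];
      ey[e] = y[f] - y[e];
      elen[e] = std::sqrt(ex[e] * ex[e] + ey[e] * ey[e]);
      L += elen[e];
      area += 0.5 * (x[e] * y[f] - x[f] * y[e]);
    }
    for (int i = 0; i < N; ++i) {
      int i0 = im(i, N);
      ds[i] = 0.5 * (elen[i0] + elen[i]);
      // tangent from neighbour chord, outward normal for ccw orientation
      double cx = x[ip(i, N)] - x[i0];
      double cy = y[ip(i, N)] - y[i0];
      double cl = std::sqrt(cx * cx + cy * cy);
      tx[i] = cx / cl; ty[i] = cy / cl;
      nx[i] = ty[i]; ny[i] = -tx[i];
      // signed Menger curvature: ccw circle of radius R -> H = -1/R
      double ux = -ex[i0], uy = -ey[i0];  // r_{i-1} - r_i ... see below
      // use u = r_i - r_{i-1}, v = r_{i+1} - r_i
      ux = ex[i0]; uy = ey[i0];
      double vx = ex[i], vy = ey[i];
      double z = ux * vy - uy * vx;
      H[i] = -2.0 * z / (elen[i0] * elen[i] * cl);
    }
  }
};

struct RoundForces {
  std::vector<double> f_curv, f_tension, f_tension_adh, f_agg, f_actin,
      f_area, f_total, vn;
  double lamL, M;
  void compute(const std::vector<double>& x, const std::vector<double>& y,
               const std::vector<double>& phi, const Par& p, double L0,
               double A_pref, const RoundGeom& g) {
    int N = (int)x.size();
    f_curv.assign(N, 0.0); f_tension.assign(N, 0.0);
    f_tension_adh.assign(N, 0.0); f_agg.assign(N, 0.0);
    f_actin.assign(N, 0.0); f_area.assign(N, 0.0); f_total.assign(N, 0.0);
    vn.assign(N, 0.0);
    lamL = lam_eff_of(g.L, L0, p);
    M = 0.0;
    for (int i = 0; i < N; ++i) M += phi[i] * g.ds[i];
    // accumulate gradient of the bending energy
    std::vector<double> gbx(N, 0.0), gby(N, 0.0);
    for (int i = 0; i < N; ++i) {
      int i0 = im(i, N), i2 = ip(i, N);
      double a = g.elen[i0], b = g.elen[i];
      double ux = g.ex[i0], uy = g.ey[i0];
      double vx = g.ex[i], vy = g.ey[i];
      double wx = ux + vx, wy = uy + vy;
      double cch = std::sqrt(wx * wx + wy * wy);
      double z = ux * vy - uy * vx;
      double Hi = -2.0 * z / (a * b * cch);
      double ci = Hi - p.Hbar * phi[i];
      double coefH = p.w * p.kappa * g.ds[i] * ci;          // dE/dH_i
      double coefds = 0.5 * p.w * p.kappa * ci * ci;        // dE/dds_i
      double pre = -2.0 / (a * b * cch);
      double uhx = ux / a, uhy = uy / a;
      double vhx = vx / b, vhy = vy / b;
      double whx = wx / cch, why = wy / cch;
      // dH/dr_{i-1} = pre * (-vy, vx) - Hi * ( -uh/a ... )
      double dmx = pre * (-vy) - Hi * (-uhx / a - whx / cch);
      double dmy = pre * (vx) - Hi * (-uhy / a - why / cch);
      double dcx = pre * (vy + uy) - Hi * (uhx / a - vhx / b);
      double dcy = pre * (-(vx + ux)) - Hi * (uhy / a - vhy / b);
      double dpx = pre * (-uy) - Hi * (vhx / b + whx / cch);
      double dpy = pre * (ux) - Hi * (vhy / b + why / cch);
      gbx[i0] += coefH * dmx; gby[i0] += coefH * dmy;
      gbx[i] += coefH * dcx; gby[i] += coefH * dcy;
      gbx[i2] += coefH * dpx; gby[i2] += coefH * dpy;
      // dds_i/dr = (d elen_{i-1} + d elen_i)/2
      gbx[i0] += coefds * 0.5 * (-uhx); gby[i0] += coefds * 0.5 * (-uhy);
      gbx[i] += coefds * 0.5 * (uhx - vhx);
      gby[i] += coefds * 0.5 * (uhy - vhy);
      gbx[i2] += coefds * 0.5 * (vhx); gby[i2] += coefds * 0.5 * (vhy);
    }
    double fare = -p.K_area * (g.area - A_pref) / A_pref;
    double aggpre = p.J_bind * p.n_s * p.lg2 / 2.0;
    for (int j = 0; j < N; ++j) {
      int j0 = im(j, N);
      double emx = g.ex[j0] / g.elen[j0], emy = g.ey[j0] / g.elen[j0];
      double epx = g.ex[j] / g.elen[j], epy = g.ey[j] / g.elen[j];
      double nxj = g.nx[j], nyj = g.ny[j];
      f_curv[j] = -(gbx[j] * nxj + gby[j] * nyj) / (p.w * g.ds[j]);
      // dL/dr_j = em - ep
      double dLn = (emx - epx) * nxj + (emy - epy) * nyj;
      double ft = -(lamL / g.ds[j]) * dLn;
      double dAdh = 0.5 * (phi[j0] + phi[j]) * (emx * nxj + emy * nyj) -
                    0.5 * (phi[j] + phi[ip(j, N)]) * (epx * nxj + epy * nyj);
      double fa = (p.alpha_adh / g.ds[j]) * dAdh;
      f_tension_adh[j] = fa;
      f_tension[j] = ft + fa;
      double dphm = (phi[j] - phi[j0]) / g.elen[j0];
      double dphp = (phi[ip(j, N)] - phi[j]) / g.elen[j];
      double gm = dphm * dphm, gp = dphp * dphp;
      // gradient of (w J n_s lg2/2) sum (dphi_e)^2/elen_e
      double dAgg = -gm * (emx * nxj + emy * nyj) + gp * (epx * nxj + epy * nyj);
      f_agg[j] = -(aggpre / g.ds[j]) * dAgg;
      f_actin[j] = p.A_actin * phi[j];
      f_area[j] = fare;
      f_total[j] = f_curv[j] + f_tension[j] + f_agg[j] + f_actin[j] +
                   f_area[j];
      vn[j] = f_total[j] / p.xi;
    }
  }
};

// ---------------------------------------------------------------------------
// Protein currents (shared 1-D periodic chain with metric)
// ---------------------------------------------------------------------------

static void fluxes_core(const std::vector<double>& phi,
                        const std::vector<double>& H,
                        const std::vector<double>& elen,
                        const std::vector<double>& ds, const Par& p,
                        std::vector<double>& Jcurv, std::vector<double>& Jdisp,
                        std::vector<double>& Jagg, std::vector<double>& Jdiff,
                        std::vector<double>& Jtot) {
  int N = (int)phi.size();
  Jcurv.resize(N); Jdisp.resize(N); Jagg.resize(N); Jdiff.resize(N);
  Jtot.resize(N);
  std::vector<double> phiss(N);
  for (int i = 0; i < N; ++i) {
    int i0 = im(i, N), i2 = ip(i, N);
    phiss[i] = ((phi[i2] - phi[i]) / elen[i] -
                (phi[i] - phi[i0]) / elen[i0]) / ds[i];
  }
  for (int e = 0; e < N; ++e) {
    int f = ip(e, N);
    double pe = 0.5 * (phi[e] + phi[f]);
    double dphi = (phi[f] - phi[e]) / elen[e];
    double dH = (H[f] - H[e]) / elen[e];
    double dphiss = (phiss[f] - phiss[e]) / elen[e];
    // advective currents carry the donor cell's density (upwind mobility:
    // positivity-preserving; identical to the centred form at second order
    // around a uniform state)
    double vc = p.Lambda * p.kappa * p.Hbar * dH;
    Jcurv[e] = vc * (vc > 0 ? phi[e] : phi[f]);
    Jdisp[e] = -p.Lambda * p.kappa * p.Hbar * p.Hbar * pe * dphi;
    double va = p.Lambda * p.J_bind * p.n_s * (dphi + p.lg2 * dphiss);
    Jagg[e] = va * (va > 0 ? phi[e] : phi[f]);
    Jdiff[e] = -p.D * dphi;
    Jtot[e] = Jcurv[e] + Jdisp[e] + Jagg[e] + Jdiff[e];
  }
}

// ---------------------------------------------------------------------------
// R-facing wrappers
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_geom_flat(NumericVector h, double dx) {
  std::vector<double> hv(h.begin(), h.end());
  FlatGeom g;
  g.compute(hv, dx);
  return List::create(_["H"] = wrap(g.H), _["elen"] = wrap(g.elen),
                      _["ds"] = wrap(g.ds), _["L"] = g.L);
}

// [[Rcpp::export]]
List cpp_geom_round(NumericVector x, NumericVector y) {
  std::vector<double> xv(x.begin(), x.end()), yv(y.begin(), y.end());
  RoundGeom g;
  g.compute(xv, yv);
  return List::create(_["H"] = wrap(g.H), _["elen"] = wrap(g.elen),
                      _["ds"] = wrap(g.ds), _["L"] = g.L,
                      _["area"] = g.area, _["nx"] = wrap(g.nx),
                      _["ny"] = wrap(g.ny), _["tx"] = wrap(g.tx),
                      _["ty"] = wrap(g.ty));
}

// [[Rcpp::export]]
List cpp_forces_flat(NumericVector h, NumericVector phi, double dx, List par,
                     double L0) {
  Par p = par_from_list(par);
  std::vector<double> hv(h.begin(), h.end()), pv(phi.begin(), phi.end());
  FlatGeom g; g.compute(hv, dx);
  FlatForces f; f.compute(hv, pv, dx, p, L0, g);
  return List::create(
      _["f_curv"] = wrap(f.f_curv), _["f_tension"] = wrap(f.f_tension),
      _["f_tension_adh"] = wrap(f.f_tension_adh),
      _["f_spring"] = wrap(f.f_spring), _["f_agg"] = wrap(f.f_agg),
      _["f_actin"] = wrap(f.f_actin), _["f_total"] = wrap(f.f_total),
      _["vn"] = wrap(f.vn), _["lam_eff"] = f.lamL, _["L"] = g.L,
      _["H"] = wrap(g.H), _["ds"] = wrap(g.ds), _["M"] = f.M);
}

// [[Rcpp::export]]
List cpp_forces_round(NumericVector x, NumericVector y, NumericVector phi,
                      List par, double L0, double A_pref) {
  Par p = par_from_list(par);
  std::vector<double> xv(x.begin(), x.end()), yv(y.begin(), y.end()),
      pv(phi.begin(), phi.end());
  RoundGeom g; g.compute(xv, yv);
  RoundForces f; f.compute(xv, yv, pv, p, L0, A_pref, g);
  return List::create(
      _["f_curv"] = wrap(f.f_curv), _["f_tension"] = wrap(f.f_tension),
      _["f_tension_adh"] = wrap(f.f_tension_adh), _["f_agg"] = wrap(f.f_agg),
      _["f_actin"] = wrap(f.f_actin), _["f_area"] = wrap(f.f_area),
      _["f_total"] = wrap(f.f_total), _["vn"] = wrap(f.vn),
      _["lam_eff"] = f.lamL, _["L"] = g.L, _["area"] = g.area,
      _["H"] = wrap(g.H), _["ds"] = wrap(g.ds), _["nx"] = wrap(g.nx),
      _["ny"] = wrap(g.ny), _["M"] = f.M);
}

// [[Rcpp::export]]
List cpp_fluxes(NumericVector phi, NumericVector H, NumericVector elen,
                NumericVector ds, List par) {
  Par p = par_from_list(par);
  std::vector<double> pv(phi.begin(), phi.end()), Hv(H.begin(), H.end()),
      ev(elen.begin(), elen.end()), dv(ds.begin(), ds.end());
  std::vector<double> Jc, Jd, Ja, Jf, Jt;
  fluxes_core(pv, Hv, ev, dv, p, Jc, Jd, Ja, Jf, Jt);
  return List::create(_["J_curv"] = wrap(Jc), _["J_disp"] = wrap(Jd),
                      _["J_agg"] = wrap(Ja), _["J_diff"] = wrap(Jf),
                      _["J_total"] = wrap(Jt));
}

// ---------------------------------------------------------------------------
// Explicit Euler steppers (chunked) with a phi-positivity sub-stepping guard
// ---------------------------------------------------------------------------

static const double PHI_LO = 0.0;
static const double PHI_HI = 1.0;
static const int MAX_HALVE = 24;

struct FlatStepper {
  std::vector<double> h, phi;
  double dx, L0;
  Par p;
  FlatGeom g;
  FlatForces f;
  std::vector<double> Jc, Jd, Ja, Jf, Jt, hn, mn, phn;

  bool attempt(double dt) {
    int N = (int)h.size();
    g.compute(h, dx);
    f.compute(h, phi, dx, p, L0, g);
    fluxes_core(phi, g.H, g.elen, g.ds, p, Jc, Jd, Ja, Jf, Jt);
    hn.resize(N); mn.resize(N); phn.resize(N);
    for (int i = 0; i < N; ++i) {
      hn[i] = h[i] + dt * f.vn[i];
      mn[i] = phi[i] * g.ds[i] - dt * (Jt[i] - Jt[im(i, N)]);
    }
    FlatGeom g2; g2.compute(hn, dx);
    bool ok = true;
    for (int i = 0; i < N; ++i) {
      phn[i] = mn[i] / g2.ds[i];
      if (!std::isfinite(phn[i]) || !std::isfinite(hn[i]) ||
          phn[i] < PHI_LO || phn[i] > PHI_HI) { ok = false; break; }
    }
    if (!ok) return false;
    h.swap(hn); phi.swap(phn);
    return true;
  }
  bool advance(double dt, int depth) {
    if (attempt(dt)) return true;
    if (depth >= MAX_HALVE) return false;
    return advance(0.5 * dt, depth + 1) && advance(0.5 * dt, depth + 1);
  }
};

// [[Rcpp::export]]
List cpp_run_flat(NumericVector h, NumericVector phi, double dx, List par,
                  double L0, double dt, int nsteps) {
  FlatStepper st;
  st.h.assign(h.begin(), h.end());
  st.phi.assign(phi.begin(), phi.end());
  st.dx = dx; st.L0 = L0; st.p = par_from_list(par);
  int done = 0, status = 0;
  for (int k = 0; k < nsteps; ++k) {
    if (!st.advance(dt, 0)) { status = 2; break; }
    ++done;
  }
  return List::create(_["h"] = wrap(st.h), _["phi"] = wrap(st.phi),
                      _["steps_done"] = done, _["t_done"] = done * dt,
                      _["status"] = status);
}

struct RoundStepper {
  std::vector<double> x, y, phi;
  double L0, A_pref;
  Par p;
  RoundGeom g;
  RoundForces f;
  std::vector<double> Jc, Jd, Ja, Jf, Jt, xn, yn, mn, phn;
  double ds_ratio;

  bool attempt(double dt) {
    int N = (int)x.size();
    g.compute(x, y);
    double dmin = g.elen[0], dmax = g.elen[0];
    for (int e = 1; e < N; ++e) {
      if (g.elen[e] < dmin) dmin = g.elen[e];
      if (g.elen[e] > dmax) dmax = g.elen[e];
    }
    ds_ratio = dmax / dmin;
    f.compute(x, y, phi, p, L0, A_pref, g);
    fluxes_core(phi, g.H, g.elen, g.ds, p, Jc, Jd, Ja, Jf, Jt);
    xn.resize(N); yn.resize(N); mn.resize(N); phn.resize(N);
    for (int i = 0; i < N; ++i) {
      xn[i] = x[i] + dt * f.vn[i] * g.nx[i];
      yn[i] = y[i] + dt * f.vn[i] * g.ny[i];
      mn[i] = phi[i] * g.ds[i] - dt * (Jt[i] - Jt[im(i, N)]);
    }
    RoundGeom g2; g2.compute(xn, yn);
    bool ok = true;
    for (int i = 0; i < N; ++i) {
      phn[i] = mn[i] / g2.ds[i];
      if (!std::isfinite(phn[i]) || !std::isfinite(xn[i]) ||
          !std::isfinite(yn[i]) || phn[i] < PHI_LO || phn[i] > PHI_HI) {
        ok = false; break;
      }
    }
    if (!ok) return false;
    x.swap(xn); y.swap(yn); phi.swap(phn);
    return true;
  }
  bool advance(double dt, int depth) {
    if (attempt(dt)) return true;
    if (depth >= MAX_HALVE) return false;
    return advance(0.5 * dt, depth + 1) && advance(0.5 * dt, depth + 1);
  }
};

// [[Rcpp::export]]
List cpp_run_round(NumericVector x, NumericVector y, NumericVector phi,
                   List par, double L0, double A_pref, double dt, int nsteps,
                   double ds_ratio_max) {
  RoundStepper st;
  st.x.assign(x.begin(), x.end());
  st.y.assign(y.begin(), y.end());
  st.phi.assign(phi.begin(), phi.end());
  st.L0 = L0; st.A_pref = A_pref; st.p = par_from_list(par);
  int done = 0, status = 0;
  for (int k = 0; k < nsteps; ++k) {
    if (!st.advance(dt, 0)) { status = 2; break; }
    ++done;
    if (st.ds_ratio > ds_ratio_max) { status = 1; break; }
  }
  return List::create(_["x"] = wrap(st.x), _["y"] = wrap(st.y),
                      _["phi"] = wrap(st.phi), _["steps_done"] = done,
                      _["t_done"] = done * dt, _["status"] = status);
}

// Segment self-intersection test for a closed polyline (O(N^2), used at
// resampling/snapshot cadence, not per step).
// [[Rcpp::export]]
bool cpp_self_intersects(NumericVector x, NumericVector y) {
  int N = x.size();
  auto orient = [&](double ax, double ay, double bx, double by, double cx,
                    double cy) {
    double v = (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
    return (v > 0.0) - (v < 0.0);
  };
  for (int i = 0; i < N; ++i) {
    int i2 = ip(i, N);
    for (int j = i + 1; j < N; ++j) {
      int j2 = ip(j, N);
      if (j == i || j2 == i || j == i2) continue;  // adjacent share a node
      double ax = x[i], ay = y[i], bx = x[i2], by = y[i2];
      double cx = x[j], cy = y[j], dx_ = x[j2], dy = y[j2];
      int o1 = orient(ax, ay, bx, by, cx, cy);
      int o2 = orient(ax, ay, bx, by, dx_, dy);
      int o3 = orient(cx, cy, dx_, dy, ax, ay);
      int o4 = orient(cx, cy, dx_, dy, bx, by);
      if (o1 != o2 && o3 != o4 && o1 != 0 && o2 != 0 && o3 != 0 && o4 != 0)
        return true;
    }
  }
  return false;
}
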