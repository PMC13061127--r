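// Fixed-step RK4 integration of elastically linked inertial clumps
// through ocean/wind forcing.  The per-clump velocity law is
//
//   xdot = u + tau * u_tau + tau * F
//   u     = (1 - alpha) v + alpha w
//   u_tau = R Dv/Dt + R (f + omega/3) v_perp - Du/Dt - (f + R omega/3) u_perp
//
// with f = f0 + beta * y, omega the vertical vorticity of v, and F the
// nonlinear spring force over the raft's link network.  Links whose
// separation exceeds the cutoff radius are pruned permanently after each
// step; clumps entering a land cell are frozen ("beached"); clumps
// leaving the ocean bounding box are frozen ("exited").
//
// Forcing fields come in two flavours:
//   * gridded (the reanalysis stand-in): bilinear in space, linear in
//     time; derivative stencils span one grid cell, one-sided inside
//     the boundary cells.  Queries are clamped to the bounding box, so
//     a clump can only be out of bounds transiently during the step in
//     which it exits.
//   * analytic (double gyre / uniform oscillating wind): exact closed
//     forms, smooth everywhere; derivative stencils use a small fixed
//     step.  Useful when interpolation kinks would otherwise dominate
//     the time-stepping error.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Grid {
  const double *u, *v;
  double x0, y0, t0, dx, dy, dt;
  int nx, ny, nt;
  double xmax, ymax, tmax;
};

struct Field {
  int type;                 // 0 grid, 1 double gyre, 2 uniform wind
  Grid g;                   // type 0
  double A, eps, T;         // type 1
  double dom_x0, dom_y0, Lx, Ly;
  double w0x, w0y, amp, dirx, diry;   // type 2
  double hx, hy, ht;        // derivative steps
  double bx0, bx1, by0, by1;          // spatial bounding box
};

inline double clampd(double z, double lo, double hi) {
  return z < lo ? lo : (z > hi ? hi : z);
}

Field make_field(const List &fld) {
  Field F;
  F.type = as<int>(fld["type"]);
  if (F.type == 0) {
    NumericVector x = fld["x"], y = fld["y"], t = fld["t"];
    NumericVector u = fld["u"], v = fld["v"];
    Grid &g = F.g;
    g.nx = x.size(); g.ny = y.size(); g.nt = t.size();
    g.x0 = x[0]; g.y0 = y[0]; g.t0 = t[0];
    g.dx = (x[g.nx - 1] - x[0]) / (g.nx - 1);
    g.dy = (y[g.ny - 1] - y[0]) / (g.ny - 1);
    g.dt = g.nt > 1 ? (t[g.nt - 1] - t[0]) / (g.nt - 1) : 1.0;
    g.xmax = x[g.nx - 1]; g.ymax = y[g.ny - 1];
    g.tmax = g.nt > 1 ? t[g.nt - 1] : t[0];
    g.u = REAL(u); g.v = REAL(v);
    F.hx = g.dx; F.hy = g.dy; F.ht = g.dt;
    F.bx0 = g.x0; F.bx1 = g.xmax; F.by0 = g.y0; F.by1 = g.ymax;
    return F;
  }
  NumericVector dom = fld["domain"];
  F.dom_x0 = dom[0]; F.dom_y0 = dom[2];
  F.Lx = dom[1] - dom[0]; F.Ly = dom[3] - dom[2];
  F.bx0 = dom[0]; F.bx1 = dom[1]; F.by0 = dom[2]; F.by1 = dom[3];
  if (F.type == 1) {
    F.A = as<double>(fld["amplitude"]);
    F.eps = as<double>(fld["epsilon"]);
    F.T = as<double>(fld["period"]);
  } else {
    NumericVector w0 = fld["w0"], dir = fld["direction"];
    F.w0x = w0[0]; F.w0y = w0[1];
    F.amp = as<double>(fld["oscillation_amplitude"]);
    F.T = as<double>(fld["period"]);
    F.dirx = dir[0]; F.diry = dir[1];
  }
  // smooth fields: small fixed stencil steps
  F.hx = F.Lx * 1e-6; F.hy = F.Ly * 1e-6; F.ht = F.T * 1e-6;
  return F;
}

// clamped trilinear sample of both components of a gridded field
inline void sample_grid(const Grid &g, double x, double y, double tt,
                        double &uo, double &vo) {
  double fx = clampd((x - g.x0) / g.dx, 0.0, g.nx - 1.0);
  double fy = clampd((y - g.y0) / g.dy, 0.0, g.ny - 1.0);
  double ft = g.nt > 1 ? clampd((tt - g.t0) / g.dt, 0.0, g.nt - 1.0) : 0.0;
  int i = (int)std::floor(fx); if (i > g.nx - 2) i = g.nx - 2; if (i < 0) i = 0;
  int j = (int)std::floor(fy); if (j > g.ny - 2) j = g.ny - 2; if (j < 0) j = 0;
  int k = 0;
  if (g.nt > 1) { k = (int)std::floor(ft); if (k > g.nt - 2) k = g.nt - 2; if (k < 0) k = 0; }
  double wx = fx - i, wy = fy - j, wt = g.nt > 1 ? ft - k : 0.0;
  const int nxy = g.nx * g.ny;
  uo = 0.0; vo = 0.0;
  const int ktop = g.nt > 1 ? 1 : 0;
  for (int dk = 0; dk <= ktop; ++dk) {
    double ck = ktop ? (dk ? wt : 1.0 - wt) : 1.0;
    for (int dj = 0; dj <= 1; ++dj) {
      double cj = dj ? wy : 1.0 - wy;
      for (int di = 0; di <= 1; ++di) {
        double ci = di ? wx : 1.0 - wx;
        int idx = (i + di) + g.nx * (j + dj) + nxy * (k + dk);
        double wgt = ci * cj * ck;
        uo += wgt * g.u[idx];
        vo += wgt * g.v[idx];
      }
    }
  }
}

inline void sample_any(const Field &F, double x, double y, double tt,
                       double &uo, double &vo) {
  if (F.type == 0) { sample_grid(F.g, x, y, tt, uo, vo); return; }
  if (F.type == 1) {
    const double pi = M_PI;
    double X = 2.0 * (x - F.dom_x0) / F.Lx;
    double Y = (y - F.dom_y0) / F.Ly;
    double s = std::sin(2.0 * pi * tt / F.T);
    double a = F.eps * s, b = 1.0 - 2.0 * F.eps * s;
    double f = a * X * X + b * X;
    double dfdX = 2.0 * a * X + b;
    uo = -(pi * F.A / F.Ly) * std::sin(pi * f) * std::cos(pi * Y);
    vo = (2.0 * pi * F.A / F.Lx) * std::cos(pi * f) * dfdX * std::sin(pi * Y);
    return;
  }
  double osc = F.amp != 0.0 ? F.amp * std::sin(2.0 * M_PI * tt / F.T) : 0.0;
  uo = F.w0x + osc * F.dirx;
  vo = F.w0y + osc * F.diry;
}

struct FieldEval {
  double ux, uy;                    // sampled components
  double dux_dx, dux_dy, dux_dt;    // derivatives of the 1st component
  double duy_dx, duy_dy, duy_dt;    // derivatives of the 2nd component
};

// value + derivatives by differencing; gridded fields get one-cell
// stencils shifted one-sided at the boundary, analytic fields a small
// centered stencil everywhere
void eval_derivs(const Field &F, double x, double y, double tt, FieldEval &e) {
  sample_any(F, x, y, tt, e.ux, e.uy);
  bool grid = F.type == 0;
  double up, vp, um, vm, den;

  double xp = x + F.hx, xm = x - F.hx;
  if (grid) { if (xp > F.bx1) xp = x; if (xm < F.bx0) xm = x; }
  sample_any(F, xp, y, tt, up, vp); sample_any(F, xm, y, tt, um, vm);
  den = xp - xm;
  e.dux_dx = den > 0 ? (up - um) / den : 0.0;
  e.duy_dx = den > 0 ? (vp - vm) / den : 0.0;

  double yp = y + F.hy, ym = y - F.hy;
  if (grid) { if (yp > F.by1) yp = y; if (ym < F.by0) ym = y; }
  sample_any(F, x, yp, tt, up, vp); sample_any(F, x, ym, tt, um, vm);
  den = yp - ym;
  e.dux_dy = den > 0 ? (up - um) / den : 0.0;
  e.duy_dy = den > 0 ? (vp - vm) / den : 0.0;

  if (!grid || F.g.nt > 1) {
    double tp = tt + F.ht, tm = tt - F.ht;
    if (grid) { if (tp > F.g.tmax) tp = tt; if (tm < F.g.t0) tm = tt; }
    sample_any(F, x, y, tp, up, vp); sample_any(F, x, y, tm, um, vm);
    den = tp - tm;
    e.dux_dt = den > 0 ? (up - um) / den : 0.0;
    e.duy_dt = den > 0 ? (vp - vm) / den : 0.0;
  } else {
    e.dux_dt = 0.0; e.duy_dt = 0.0;
  }
}

struct Params {
  double alpha, R, tau, f0, beta;
  double ell, kappa0, dcut, cutoff;
};

// spring forces over the active link set (Newton's third law by
// construction: each pair contributes equal and opposite terms)
void spring_forces(const std::vector<double> &px, const std::vector<double> &py,
                   const IntegerVector &ei, const IntegerVector &ej,
                   const std::vector<bool> &edge_on, const Params &p,
                   std::vector<double> &Fx, std::vector<double> &Fy) {
  std::fill(Fx.begin(), Fx.end(), 0.0);
  std::fill(Fy.begin(), Fy.end(), 0.0);
  const int E = ei.size();
  for (int e = 0; e < E; ++e) {
    if (!edge_on[e]) continue;
    int a = ei[e] - 1, b = ej[e] - 1;
    double rx = px[a] - px[b], ry = py[a] - py[b];
    double r = std::sqrt(rx * rx + ry * ry);
    if (r == 0.0) continue;                 // coincident: zero contribution
    if (r > p.cutoff) continue;             // pruned at end of step
    double kap = p.kappa0 / (std::exp((r - 2.0 * p.ell) / p.dcut) + 1.0);
    double c = -kap * (1.0 - p.ell / r);
    Fx[a] += c * rx; Fy[a] += c * ry;
    Fx[b] -= c * rx; Fy[b] -= c * ry;
  }
}

// velocity law for one clump at (x, y, t) given its spring force
inline void clump_rhs(const Field &go, const Field &gw, const Params &p,
                      double x, double y, double tt,
                      double Fx, double Fy, double &dx, double &dy) {
  double a = p.alpha;
  double ux, uy;
  double utau_x = 0.0, utau_y = 0.0;
  if (p.tau == 0.0) {
    double vx, vy, wx, wy;
    sample_any(go, x, y, tt, vx, vy);
    sample_any(gw, x, y, tt, wx, wy);
    ux = (1.0 - a) * vx + a * wx;
    uy = (1.0 - a) * vy + a * wy;
  } else {
    FieldEval ev, ew;
    eval_derivs(go, x, y, tt, ev);
    eval_derivs(gw, x, y, tt, ew);
    ux = (1.0 - a) * ev.ux + a * ew.ux;
    uy = (1.0 - a) * ev.uy + a * ew.uy;
    // carrying-field derivatives: linear combination of per-field stencils
    double dux_dx = (1 - a) * ev.dux_dx + a * ew.dux_dx;
    double dux_dy = (1 - a) * ev.dux_dy + a * ew.dux_dy;
    double dux_dt = (1 - a) * ev.dux_dt + a * ew.dux_dt;
    double duy_dx = (1 - a) * ev.duy_dx + a * ew.duy_dx;
    double duy_dy = (1 - a) * ev.duy_dy + a * ew.duy_dy;
    double duy_dt = (1 - a) * ev.duy_dt + a * ew.duy_dt;
    double f = p.f0 + p.beta * y;
    double omega = ev.duy_dx - ev.dux_dy;   // vorticity of the ocean field
    double Dv_x = ev.dux_dt + ev.ux * ev.dux_dx + ev.uy * ev.dux_dy;
    double Dv_y = ev.duy_dt + ev.ux * ev.duy_dx + ev.uy * ev.duy_dy;
    double Du_x = dux_dt + ux * dux_dx + uy * dux_dy;
    double Du_y = duy_dt + ux * duy_dx + uy * duy_dy;
    utau_x = p.R * Dv_x + p.R * (f + omega / 3.0) * (-ev.uy)
           - Du_x - (f + p.R * omega / 3.0) * (-uy);
    utau_y = p.R * Dv_y + p.R * (f + omega / 3.0) * (ev.ux)
           - Du_y - (f + p.R * omega / 3.0) * (ux);
  }
  dx = ux + p.tau * utau_x + p.tau * Fx;
  dy = uy + p.tau * utau_y + p.tau * Fy;
}

} // namespace

// [[Rcpp::export(name = ".ebomb_integrate")]]
List ebomb_integrate(NumericMatrix pos0, IntegerVector ei, IntegerVector ej,
                     List ocean, List wind, List params,
                     double t0, double dt_int, int n_steps, int sample_every,
                     Nullable<LogicalMatrix> land_mask) {
  const int M = pos0.nrow();
  Field go = make_field(ocean);
  Field gw = make_field(wind);
  Params p;
  p.alpha = as<double>(params["alpha"]); p.R = as<double>(params["R"]);
  p.tau = as<double>(params["tau"]); p.f0 = as<double>(params["f0"]);
  p.beta = as<double>(params["beta"]); p.ell = as<double>(params["ell"]);
  p.kappa0 = as<double>(params["kappa0"]); p.dcut = as<double>(params["d"]);
  p.cutoff = as<double>(params["cutoff_radius"]);

  bool has_mask = land_mask.isNotNull() && go.type == 0;
  LogicalMatrix mask;
  if (has_mask) mask = LogicalMatrix(land_mask);

  const int K = n_steps / sample_every + 1;
  NumericVector out_pos(M * 2 * K);
  out_pos.attr("dim") = IntegerVector::create(M, 2, K);
  IntegerMatrix out_status(M, K);       // 0 active, 1 beached, 2 exited
  IntegerVector exit_step(M, NA_INTEGER);

  std::vector<double> px(M), py(M), Fx(M), Fy(M);
  std::vector<double> k1x(M), k1y(M), k2x(M), k2y(M),
                      k3x(M), k3y(M), k4x(M), k4y(M),
                      tx(M), ty(M);
  std::vector<int> status(M, 0);
  for (int m = 0; m < M; ++m) { px[m] = pos0(m, 0); py[m] = pos0(m, 1); }

  const int E = ei.size();
  std::vector<bool> edge_on(E, true);

  auto rhs = [&](const std::vector<double> &qx, const std::vector<double> &qy,
                 double tt, std::vector<double> &ox, std::vector<double> &oy) {
    spring_forces(qx, qy, ei, ej, edge_on, p, Fx, Fy);
    for (int m = 0; m < M; ++m) {
      if (status[m] != 0) { ox[m] = 0.0; oy[m] = 0.0; continue; }
      clump_rhs(go, gw, p, qx[m], qy[m], tt, Fx[m], Fy[m], ox[m], oy[m]);
    }
  };

  auto record = [&](int slot) {
    for (int m = 0; m < M; ++m) {
      out_pos[m + M * 0 + 2 * M * slot] = px[m];
      out_pos[m + M * 1 + 2 * M * slot] = py[m];
      out_status(m, slot) = status[m];
    }
  };

  auto check_events = [&](int m, int step) {
    if (px[m] < go.bx0 || px[m] > go.bx1 || py[m] < go.by0 || py[m] > go.by1) {
      status[m] = 2; exit_step[m] = step;
    } else if (has_mask) {
      int ci = (int)std::floor((px[m] - go.g.x0) / go.g.dx);
      int cj = (int)std::floor((py[m] - go.g.y0) / go.g.dy);
      if (ci > go.g.nx - 2) ci = go.g.nx - 2;
      if (cj > go.g.ny - 2) cj = go.g.ny - 2;
      if (mask(ci, cj)) status[m] = 1;
    }
  };

  // clumps seeded on land or outside the domain are flagged at once
  for (int m = 0; m < M; ++m) check_events(m, 0);
  record(0);

  for (int s = 0; s < n_steps; ++s) {
    double tt = t0 + s * dt_int;
    double h = dt_int;
    rhs(px, py, tt, k1x, k1y);
    for (int m = 0; m < M; ++m) { tx[m] = px[m] + 0.5 * h * k1x[m]; ty[m] = py[m] + 0.5 * h * k1y[m]; }
    rhs(tx, ty, tt + 0.5 * h, k2x, k2y);
    for (int m = 0; m < M; ++m) { tx[m] = px[m] + 0.5 * h * k2x[m]; ty[m] = py[m] + 0.5 * h * k2y[m]; }
    rhs(tx, ty, tt + 0.5 * h, k3x, k3y);
    for (int m = 0; m < M; ++m) { tx[m] = px[m] + h * k3x[m]; ty[m] = py[m] + h * k3y[m]; }
    rhs(tx, ty, tt + h, k4x, k4y);
    for (int m = 0; m < M; ++m) {
      if (status[m] != 0) continue;
      px[m] += h / 6.0 * (k1x[m] + 2.0 * k2x[m] + 2.0 * k3x[m] + k4x[m]);
      py[m] += h / 6.0 * (k1y[m] + 2.0 * k2y[m] + 2.0 * k3y[m] + k4y[m]);
      if (!std::isfinite(px[m]) || !std::isfinite(py[m]))
        stop("integration diverged: non-finite position for clump %d at step %d",
             m + 1, s + 1);
      check_events(m, s + 1);
    }
    // permanent disaggregation of over-stretched links
    for (int e = 0; e < E; ++e) {
      if (!edge_on[e]) continue;
      int a = ei[e] - 1, b = ej[e] - 1;
      double rx = px[a] - px[b], ry = py[a] - py[b];
      if (std::sqrt(rx * rx + ry * ry) > p.cutoff) edge_on[e] = false;
    }
    if ((s + 1) % sample_every == 0) record((s + 1) / sample_every);
  }

  LogicalVector edge_final(E);
  for (int e = 0; e < E; ++e) edge_final[e] = edge_on[e];
  return List::create(_["positions"] = out_pos,
                      _["status"] = out_status,
                      _["exit_step"] = exit_step,
                      _["edge_active"] = edge_final);
}
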