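// Steady-state two-node heat/water balance of a perched bird with the
// ordered thermoregulatory cascade:
//   1 reduce ptiloerection  2 stretch the body  3 raise flesh conductivity
//   4 raise core temperature (to 44 C) coupled with respiratory rate (to 7.5x)
//   5 raise skin wetness (closure)
// Cold side: reduce baseline skin wetness toward 0, then raise heat
// generation above basal.
//
// Nodes: core (Tb, regulated) -> skin (Ts) through a flesh shell, skin ->
// plumage surface (Tp) through the plumage layer, surface <-> environment by
// forced/free convection, longwave exchange (half sky, half ground view) and
// absorbed shortwave. Respiratory evaporation is drawn from the core,
// cutaneous evaporation from the skin.
#include <Rcpp.h>
using namespace Rcpp;

static const double SIGMA  = 5.670374419e-8; // W m-2 K-4
static const double RV     = 461.5;          // J kg-1 K-1, water vapour
static const double LAMBDA = 2.406e6;        // J kg-1 latent heat
static const double KAIR   = 0.0263;         // W m-1 K-1
static const double NUAIR  = 1.6e-5;         // m2 s-1 kinematic viscosity
static const double RHOAIR = 1.13;           // kg m-3
static const double CPAIR  = 1006.0;         // J kg-1 K-1
static const double EO2    = 20.1;           // J per mL O2
static const double FO2    = 0.2094;         // O2 fraction of air
static const double EXTR   = 0.2;            // O2 extraction efficiency
static const double DVAP   = 2.5e-5;         // m2 s-1 vapour diffusivity

struct Bird {
  double mass_g, density, depth, kplume, kfmin, kfmax, tbnorm, tbmax,
         pmax, rmin, rmax, smin, wet0, alpha, qbasal, tffrac, eps, qmaxmult;
  double asil; // posture-independent silhouette area (rest-shape A / 2)
};
struct Env { double ta, rh, sol, wind, tsky, tgnd; };
// controls: s ptiloerection multiplier, r shape ratio, kf flesh conductivity,
// tb core temperature, p respiratory multiplier, w skin wetness, qgen W
struct Ctl { double s, r, kf, tb, p, w, qgen; };

static Bird as_bird(const NumericVector& b);

static double esat_kpa(double T) {
  return 0.61094 * exp(17.625 * T / (T + 243.04));
}
static double rho_vap(double e_kpa, double T) {
  return e_kpa * 1000.0 / (RV * (T + 273.15));
}

struct Geom { double A, b, D, V; };
static Geom geom(const Bird& bd, double r) {
  Geom g;
  g.V = bd.mass_g / 1000.0 / bd.density;
  double bs = cbrt(3.0 * g.V / (4.0 * M_PI * r));
  double a = r * bs;
  if (r <= 1.0 + 1e-9) {
    g.A = 4.0 * M_PI * bs * bs;
  } else {
    double e = sqrt(1.0 - (bs * bs) / (a * a));
    g.A = 2.0 * M_PI * bs * bs * (1.0 + a / (bs * e) * asin(e));
  }
  g.b = bs;
  g.D = cbrt(g.V);
  return g;
}

static Bird as_bird(const NumericVector& b) {
  Bird bd;
  bd.mass_g = b[0];  bd.density = b[1]; bd.depth = b[2];  bd.kplume = b[3];
  bd.kfmin = b[4];   bd.kfmax = b[5];   bd.tbnorm = b[6]; bd.tbmax = b[7];
  bd.pmax = b[8];    bd.rmin = b[9];    bd.rmax = b[10];  bd.smin = b[11];
  bd.wet0 = b[12];   bd.alpha = b[13];  bd.qbasal = b[14];
  bd.tffrac = b[15]; bd.eps = b[16];    bd.qmaxmult = b[17];
  bd.asil = geom(bd, bd.rmin).A / 2.0;
  return bd;
}


// Illinois false-position root finder on a bracket with f(a), f(b) of
// opposite sign; superlinear and robust for the smooth balances here
template <class F>
static double illinois(F f, double a, double b, double fa, double fb,
                       double xtol, double ftol, double* fx_out) {
  double x = 0.5 * (a + b), fx = fa;
  for (int i = 0; i < 60; ++i) {
    x = b - fb * (b - a) / (fb - fa);
    double lo = std::min(a, b), hi = std::max(a, b);
    if (!(x > lo && x < hi)) x = 0.5 * (a + b);
    fx = f(x);
    if (fabs(fx) <= ftol || fabs(b - a) <= xtol) break;
    if ((fx > 0) == (fa > 0)) { a = x; fa = fx; fb *= 0.5; }
    else { b = x; fb = fx; fa *= 0.5; }
  }
  if (fx_out) *fx_out = fx;
  return x;
}

struct Inner {
  double ts, tp, resid, mresp, mcut, qresp, qcut, qsol, qconv, qlw;
  double A, gp, gf, hc;
};

static Inner inner_solve(const Bird& bd, const Env& ev, const Ctl& c) {
  Inner in;
  Geom g = geom(bd, c.r);
  in.A = g.A;
  in.gp = bd.kplume * g.A / (bd.depth * c.s);
  in.gf = c.kf * g.A / (bd.tffrac * g.b);
  double Re = std::max(ev.wind, 0.05) * g.D / NUAIR;
  double Nu = std::max(2.0, 0.35 * pow(Re, 0.6));
  in.hc = Nu * KAIR / g.D;
  double hm = in.hc / (RHOAIR * CPAIR);
  in.qsol = bd.alpha * bd.asil * ev.sol;
  double rva = rho_vap(ev.rh / 100.0 * esat_kpa(ev.ta), ev.ta);
  double vo2 = c.qgen / EO2;                       // mL O2 s-1
  double vent = vo2 * 1e-6 / (FO2 * EXTR) * c.p;   // m3 s-1
  in.mresp = vent * std::max(0.0, rho_vap(esat_kpa(c.tb), c.tb) - rva);
  in.qresp = in.mresp * LAMBDA;
  double tsky4 = pow(ev.tsky + 273.15, 4), tgnd4 = pow(ev.tgnd + 273.15, 4);

  // surface temperature for a given skin temperature (Newton)
  struct {
    double gp, qsol, hcA, epsSA, ta, tsky4, tgnd4;
    double operator()(double ts) const {
      double tp = ta;
      for (int i = 0; i < 80; ++i) {
        double tk = tp + 273.15;
        double F = gp * (ts - tp) + qsol - hcA * (tp - ta)
                   - epsSA * (tk * tk * tk * tk - 0.5 * tsky4 - 0.5 * tgnd4);
        double dF = -gp - hcA - 4.0 * epsSA * tk * tk * tk;
        double step = F / dF;
        tp -= step;
        if (fabs(step) < 1e-11) break;
      }
      return tp;
    }
  } tp_of;
  tp_of.gp = in.gp; tp_of.qsol = in.qsol; tp_of.hcA = in.hc * g.A;
  tp_of.epsSA = bd.eps * SIGMA * g.A; tp_of.ta = ev.ta;
  tp_of.tsky4 = tsky4; tp_of.tgnd4 = tgnd4;

  // skin node balance; cutaneous vapour crosses the plumage air layer and
  // the boundary layer in series
  double gv = 1.0 / (1.0 / hm + bd.depth * c.s / DVAP);
  double cutc = gv * g.A * c.w; // kg m-3 -> kg s-1 factor
  double hcA = in.hc * g.A, epsSA = bd.eps * SIGMA * g.A;
  // 2-D Newton on the skin and surface node balances (analytic Jacobian),
  // nested false-position as fallback near the evaporation kink
  double ts = 0.5 * (c.tb + ev.ta), tp = ev.ta;
  bool ok = false;
  for (int it = 0; it < 50; ++it) {
    double rs = rho_vap(esat_kpa(ts), ts);
    double wetden = rs - rva;
    double mc = cutc * std::max(0.0, wetden);
    double tk = tp + 273.15;
    double f1v = in.gf * (c.tb - ts) - in.gp * (ts - tp) - mc * LAMBDA;
    double f2v = in.gp * (ts - tp) + in.qsol - hcA * (tp - ev.ta)
                 - epsSA * (tk * tk * tk * tk - 0.5 * tsky4 - 0.5 * tgnd4);
    double drho = (wetden > 0)
      ? rs * (17.625 * 243.04 / ((ts + 243.04) * (ts + 243.04))
              - 1.0 / (ts + 273.15))
      : 0.0;
    double j11 = -in.gf - in.gp - LAMBDA * cutc * drho;
    double j12 = in.gp;
    double j21 = in.gp;
    double j22 = -in.gp - hcA - 4.0 * epsSA * tk * tk * tk;
    double det = j11 * j22 - j12 * j21;
    if (det == 0) break;
    double dts = (f1v * j22 - f2v * j12) / det;
    double dtp = (j11 * f2v - j21 * f1v) / det;
    if (dts > 30) dts = 30; else if (dts < -30) dts = -30;
    if (dtp > 30) dtp = 30; else if (dtp < -30) dtp = -30;
    ts -= dts; tp -= dtp;
    if (fabs(dts) < 1e-9 && fabs(dtp) < 1e-9) { ok = true; break; }
  }
  if (!ok) {
    auto F1 = [&](double tss) {
      double tpp = tp_of(tss);
      double mc = cutc * std::max(0.0, rho_vap(esat_kpa(tss), tss) - rva);
      return in.gf * (c.tb - tss) - in.gp * (tss - tpp) - mc * LAMBDA;
    };
    double lo = std::min(ev.ta, c.tb) - 80.0;
    double hi = std::max(ev.ta, c.tb) + 80.0;
    double flo = F1(lo), fhi = F1(hi);
    if (flo < 0) ts = lo;
    else if (fhi > 0) ts = hi;
    else ts = illinois(F1, lo, hi, flo, fhi, 1e-8, 1e-9, nullptr);
    tp = tp_of(ts);
  }
  in.ts = ts;
  in.tp = tp;
  in.mcut = cutc * std::max(0.0, rho_vap(esat_kpa(ts), ts) - rva);
  in.qcut = in.mcut * LAMBDA;
  double tk = in.tp + 273.15;
  in.qconv = in.hc * g.A * (in.tp - ev.ta);
  in.qlw = bd.eps * SIGMA * g.A *
           (tk * tk * tk * tk - 0.5 * tsky4 - 0.5 * tgnd4);
  in.resid = c.qgen - in.qresp - in.gf * (c.tb - ts);
  return in;
}

static double resid_of(const Bird& bd, const Env& ev, const Ctl& c) {
  return inner_solve(bd, ev, c).resid;
}

// set cascade control k (1..5) to rest + u * (limit - rest)
static void set_stage(Ctl& c, const Bird& bd, int k, double u) {
  switch (k) {
  case 1: c.s  = 1.0 + u * (bd.smin - 1.0); break;
  case 2: c.r  = bd.rmin + u * (bd.rmax - bd.rmin); break;
  case 3: c.kf = bd.kfmin + u * (bd.kfmax - bd.kfmin); break;
  case 4: c.tb = bd.tbnorm + u * (bd.tbmax - bd.tbnorm);
          c.p  = 1.0 + u * (bd.pmax - 1.0); break;
  case 5: c.w  = bd.wet0 + u * (1.0 - bd.wet0); break;
  }
}

// state vector layout shared with the R wrapper
static NumericVector pack_state(const Bird& bd, const Env& ev, const Ctl& c,
                                int stage, int flag, const double* stat) {
  Inner in = inner_solve(bd, ev, c);
  double water = (in.mresp + in.mcut) * 3.6e6; // kg/s -> g/h
  NumericVector out = NumericVector::create(
    _["stage"] = (double)stage, _["flag"] = (double)flag,
    _["tb"] = c.tb, _["ts"] = in.ts, _["tsurf"] = in.tp,
    _["ptilo"] = c.s, _["shape"] = c.r, _["kflesh"] = c.kf,
    _["pmult"] = c.p, _["wet"] = c.w, _["qgen"] = c.qgen,
    _["qsol"] = in.qsol, _["qconv"] = in.qconv, _["qlw"] = in.qlw,
    _["qresp"] = in.qresp, _["qcut"] = in.qcut,
    _["water_gph"] = water, _["resid"] = in.resid);
  NumericVector st(5);
  for (int i = 0; i < 5; ++i) st[i] = stat[i];
  out.attr("stage_status") = st;
  return out;
}

// build the control vector from normalized stage engagements u[0..4]
static Ctl ctl_from_u(const Bird& bd, const double* u) {
  Ctl c; c.s = 1.0; c.r = bd.rmin; c.kf = bd.kfmin; c.tb = bd.tbnorm;
  c.p = 1.0; c.w = bd.wet0; c.qgen = bd.qbasal;
  for (int k = 1; k <= 5; ++k) set_stage(c, bd, k, u[k - 1]);
  return c;
}

// stage status codes: 0 skipped (rest is the dissipating limit here),
// 1 saturated at limit, 2 partially engaged, 3 at rest (not reached)
static NumericVector solve_env(const Bird& bd, const Env& ev, double tol) {
  Ctl c; c.s = 1.0; c.r = bd.rmin; c.kf = bd.kfmin; c.tb = bd.tbnorm;
  c.p = 1.0; c.w = bd.wet0; c.qgen = bd.qbasal;
  double stat[5] = {3, 3, 3, 3, 3};
  int stage = 0, flag = 0;
  double R = resid_of(bd, ev, c);

  if (R < -tol) {
    // cold side: shed baseline wetness, then raise metabolic heat
    Ctl c0 = c; c0.w = 0.0;
    double R0 = resid_of(bd, ev, c0);
    if (fabs(R0) <= tol) {
      c = c0;
    } else if (R0 > tol) { // root in (0, wet0)
      auto f = [&](double w) { Ctl cm = c; cm.w = w; return resid_of(bd, ev, cm); };
      c.w = illinois(f, 0.0, bd.wet0, R0, R, 1e-12, 0.5 * tol, nullptr);
    } else { // still losing heat at w = 0: raise qgen
      c.w = 0.0;
      double qhi = bd.qbasal * bd.qmaxmult;
      Ctl cq = c; cq.qgen = qhi;
      if (resid_of(bd, ev, cq) < -tol) {
        c = cq; flag = 2; // unmet cold load
      } else {
        auto f = [&](double q) {
          Ctl cm = c; cm.qgen = q; return resid_of(bd, ev, cm);
        };
        Ctl clo = c; clo.qgen = bd.qbasal;
        c.qgen = illinois(f, bd.qbasal, qhi, resid_of(bd, ev, clo),
                          resid_of(bd, ev, cq), 1e-10, 0.5 * tol, nullptr);
      }
    }
  } else if (R > tol) {
    // hot side: minimal water loss over the cascade-compliant states.
    // A compliant state has one (at most) partially engaged stage, any mix
    // of saturated and skipped (rest-as-dissipating-limit) stages below it
    // and resting stages above it: enumerate every below-pattern and solve
    // the partial stage exactly, then keep the water minimum.
    double u[5];
    auto resid_u = [&](const double* uu) {
      return resid_of(bd, ev, ctl_from_u(bd, uu));
    };
    auto water_u = [&](const double* uu) {
      Inner in = inner_solve(bd, ev, ctl_from_u(bd, uu));
      return in.mresp + in.mcut;
    };
    // solve stage k between engagements with residuals of opposite sign
    auto bisect_stage = [&](double* uu, int k, double a, double Ra,
                            double b2, double Rb) {
      auto f = [&](double x) { uu[k - 1] = x; return resid_u(uu); };
      uu[k - 1] = illinois(f, a, b2, Ra, Rb, 1e-11, 0.5 * tol, nullptr);
    };
    double best_w = HUGE_VAL;
    double best_u[5] = {1, 1, 1, 1, 1};
    bool found = false;
    for (int k = 1; k <= 5; ++k) {
      int npat = 1 << (k - 1);
      for (int pat = 0; pat < npat; ++pat) {
        for (int j = 0; j < 5; ++j) u[j] = 0.0;
        for (int j = 0; j < k - 1; ++j) u[j] = (pat >> j) & 1 ? 1.0 : 0.0;
        u[k - 1] = 1.0;
        double R1 = resid_u(u);
        bool cand = false;
        if (fabs(R1) <= tol) {
          cand = true;
        } else {
          u[k - 1] = 0.0;
          double R0 = resid_u(u);
          if (fabs(R0) <= tol) {
            cand = true;
          } else if ((R0 > 0) != (R1 > 0)) {
            bisect_stage(u, k, 0.0, R0, 1.0, R1);
            cand = true;
          }
        }
        if (cand) {
          double w = water_u(u);
          if (w < best_w) {
            best_w = w;
            std::copy(u, u + 5, best_u);
            found = true;
          }
        }
      }
    }
    if (!found) flag = 1; // unmet heat load even fully engaged
    std::copy(best_u, best_u + 5, u);
    c = ctl_from_u(bd, u);
    // derive stage + statuses from the engagement vector
    for (int k = 5; k >= 1; --k) if (u[k - 1] > 0) { stage = k; break; }
    for (int k = 1; k <= 5; ++k) {
      if (u[k - 1] >= 1.0) stat[k - 1] = 1;
      else if (u[k - 1] > 0.0) stat[k - 1] = 2;
      else stat[k - 1] = (k < stage) ? 0 : 3;
    }
    if (flag == 1) stage = 5;
  }
  return pack_state(bd, ev, c, stage, flag, stat);
}

static Env row_env(const NumericMatrix& m, int i) {
  Env e;
  e.ta = m(i, 0); e.rh = m(i, 1); e.sol = m(i, 2);
  e.wind = m(i, 3); e.tsky = m(i, 4); e.tgnd = m(i, 5);
  return e;
}

// [[Rcpp::export(name = ".solve_env_cpp")]]
NumericVector solve_env_cpp(NumericVector env, NumericVector bird, double tol) {
  Bird bd = as_bird(bird);
  Env ev; ev.ta = env[0]; ev.rh = env[1]; ev.sol = env[2];
  ev.wind = env[3]; ev.tsky = env[4]; ev.tgnd = env[5];
  return solve_env(bd, ev, tol);
}

// per hour: water loss under the better of open/shade, plus diagnostics
// columns: water_gph, habitat (0 open, 1 shade), tb, stage, flag, water_open,
// water_shade
// [[Rcpp::export(name = ".solve_day_cpp")]]
NumericMatrix solve_day_cpp(NumericMatrix open_env, NumericMatrix shade_env,
                            NumericVector bird, double tol, bool open_only) {
  Bird bd = as_bird(bird);
  int n = open_env.nrow();
  NumericMatrix out(n, 7);
  for (int i = 0; i < n; ++i) {
    NumericVector so = solve_env(bd, row_env(open_env, i), tol);
    double wo = so["water_gph"];
    if (open_only) {
      out(i, 0) = wo; out(i, 1) = 0; out(i, 2) = so["tb"];
      out(i, 3) = so["stage"]; out(i, 4) = so["flag"];
      out(i, 5) = wo; out(i, 6) = NA_REAL;
      continue;
    }
    NumericVector ss = solve_env(bd, row_env(shade_env, i), tol);
    double ws = ss["water_gph"];
    bool shade = ws < wo;
    const NumericVector& pick = shade ? ss : so;
    out(i, 0) = shade ? ws : wo;
    out(i, 1) = shade ? 1 : 0;
    out(i, 2) = pick["tb"]; out(i, 3) = pick["stage"];
    out(i, 4) = pick["flag"];
    out(i, 5) = wo; out(i, 6) = ws;
  }
  colnames(out) = CharacterVector::create("water_gph", "habitat", "tb",
                                          "stage", "flag", "water_open",
                                          "water_shade");
  return out;
}
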