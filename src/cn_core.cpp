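// Conservative Crank-Nicolson integrator for the radially symmetric
// tumor / CAR T-cell reaction-diffusion system.
//
// Discretization: node-centered finite volumes on r_i = i*dr with face
// areas ~ r^2, which makes the origin a zero-area face (no 1/r^2
// singularity) and conserves mass exactly under zero-flux boundaries.
// The thresholded tumor diffusivity is evaluated once per step from the
// beginning-of-step state (lagged mask), preserving tridiagonality.
// Reaction terms are handled by a Heun (trapezoidal) predictor-corrector
// around the CN diffusion solve (reaction_order = 2), or by a single
// explicit evaluation (reaction_order = 1).

#include <Rcpp.h>
using namespace Rcpp;

static const double EPS_DENSITY = 1e-12;

struct Params {
  double a, b, DT, ustar;          // tumor
  double DC, d, s, l, j, k, m, q;  // CAR T
};

static inline double lysis(double u, double v, const Params &p) {
  if (u <= 0.0 || v <= 0.0) return 0.0;
  double ratio = std::pow(v / std::max(u, EPS_DENSITY), p.l);
  if (!R_finite(ratio)) return p.d * u;  // saturated Hill term
  return p.d * ratio / (p.s + ratio) * u;
}

static inline double f1(double u, double v, const Params &p) {
  return p.a * u * (1.0 - p.b * u) - lysis(u, v, p);
}

static inline double f2(double u, double v, const Params &p) {
  double D = lysis(u, v, p);
  double prolif = (p.k + D * D > 0.0) ? p.j * D * D / (p.k + D * D) : 0.0;
  return prolif * v - p.m * v - p.q * u * v;
}

// Thomas algorithm; a = sub, b = diag, c = super, rhs overwritten with x
static void thomas(std::vector<double> &a, std::vector<double> &b,
                   std::vector<double> &c, std::vector<double> &rhs) {
  int n = b.size();
  for (int i = 1; i < n; ++i) {
    double w = a[i] / b[i - 1];
    b[i] -= w * c[i - 1];
    rhs[i] -= w * rhs[i - 1];
  }
  rhs[n - 1] /= b[n - 1];
  for (int i = n - 2; i >= 0; --i)
    rhs[i] = (rhs[i] - c[i] * rhs[i + 1]) / b[i];
}

// Face diffusivities for the tumor field from the lagged state.
// mask_rule 0: threshold applied to the face-averaged density;
// mask_rule 1: arithmetic mean of the two node diffusivities;
// mask_rule 2: full diffusivity if either adjacent node is above
//              threshold (an above-threshold node sheds mass across both
//              of its faces at the full rate).
static void tumor_face_D(const std::vector<double> &u, const Params &p,
                         int mask_rule, std::vector<double> &Df) {
  int nf = Df.size();
  for (int i = 0; i < nf; ++i) {
    if (mask_rule == 0) {
      Df[i] = (0.5 * (u[i] + u[i + 1]) > p.ustar) ? p.DT : 0.0;
    } else if (mask_rule == 1) {
      double di = (u[i] > p.ustar) ? p.DT : 0.0;
      double dj = (u[i + 1] > p.ustar) ? p.DT : 0.0;
      Df[i] = 0.5 * (di + dj);
    } else if (mask_rule == 2) {
      Df[i] = (u[i] > p.ustar || u[i + 1] > p.ustar) ? p.DT : 0.0;
    } else {
      // linear ramp of width ramp_frac*u_star above the threshold
      double uf = 0.5 * (u[i] + u[i + 1]);
      double frac = (uf - p.ustar) / (0.5 * p.ustar);
      frac = std::min(std::max(frac, 0.0), 1.0);
      Df[i] = p.DT * frac;
    }
  }
}

// One CN solve for a single field given face diffusivities and an
// explicit per-node forcing (reaction + source), already multiplied by
// nothing -- `force` enters as dt * force.
// bc = 0: Neumann (zero flux) at r_max; bc = 1: Dirichlet value bcval.
static void cn_solve(const std::vector<double> &x,
                     const std::vector<double> &Df,
                     const std::vector<double> &gfac,  // 4*pi*r_f^2/dr per face
                     const std::vector<double> &w,     // cell volumes
                     double dt, const std::vector<double> &force,
                     int bc, double bcval, std::vector<double> &out) {
  int n = x.size();
  std::vector<double> sub(n, 0.0), diag(n, 0.0), sup(n, 0.0), rhs(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double cL = (i > 0) ? Df[i - 1] * gfac[i - 1] / w[i] : 0.0;
    double cR = (i < n - 1) ? Df[i] * gfac[i] / w[i] : 0.0;
    double expl = cL * ((i > 0 ? x[i - 1] : 0.0) - x[i]) +
                  cR * ((i < n - 1 ? x[i + 1] : 0.0) - x[i]);
    diag[i] = 1.0 + 0.5 * dt * (cL + cR);
    sub[i] = -0.5 * dt * cL;
    sup[i] = -0.5 * dt * cR;
    rhs[i] = x[i] + 0.5 * dt * expl + dt * force[i];
  }
  if (bc == 1) {  // Dirichlet at the outer node
    sub[n - 1] = 0.0;
    diag[n - 1] = 1.0;
    rhs[n - 1] = bcval;
  }
  thomas(sub, diag, sup, rhs);
  out = rhs;
}

static double detect_radius(const std::vector<double> &u, double dr,
                            double ud) {
  int n = u.size();
  for (int i = n - 1; i >= 0; --i) {
    if (u[i] >= ud) {
      if (i == n - 1) return (n - 1) * dr;
      // u[i+1] < ud here; linear interpolation inside the bracket
      double frac = (u[i] - ud) / (u[i] - u[i + 1]);
      return i * dr + frac * dr;
    }
  }
  return 0.0;
}

// tumor cells inside the ball of radius rdet (overlap volumes per cell)
static double cells_within(const std::vector<double> &u,
                           const std::vector<double> &rin,
                           const std::vector<double> &rout, double rdet) {
  if (rdet <= 0.0) return 0.0;
  double tot = 0.0;
  const double c = 4.0 * M_PI / 3.0;
  for (size_t i = 0; i < u.size(); ++i) {
    double ri = std::min(rin[i], rdet), ro = std::min(rout[i], rdet);
    if (ro > ri) tot += u[i] * c * (ro * ro * ro - ri * ri * ri);
    if (rin[i] >= rdet) break;
  }
  return tot;
}

static Params make_params(List par) {
  Params p;
  p.a = par["a"]; p.b = par["b"]; p.DT = par["D_T"]; p.ustar = par["u_star"];
  p.DC = par["D_C"]; p.d = par["d"]; p.s = par["s"]; p.l = par["l"];
  p.j = par["j"]; p.k = par["k"]; p.m = par["m"]; p.q = par["q"];
  return p;
}

static void geometry(int n, double dr, std::vector<double> &gfac,
                     std::vector<double> &w, std::vector<double> &rin,
                     std::vector<double> &rout) {
  gfac.assign(n - 1, 0.0);
  w.assign(n, 0.0);
  rin.assign(n, 0.0);
  rout.assign(n, 0.0);
  double rmax = (n - 1) * dr;
  for (int i = 0; i < n - 1; ++i) {
    double rf = (i + 0.5) * dr;
    gfac[i] = 4.0 * M_PI * rf * rf / dr;
  }
  for (int i = 0; i < n; ++i) {
    rin[i] = std::max(i * dr - 0.5 * dr, 0.0);
    rout[i] = std::min(i * dr + 0.5 * dr, rmax);
    w[i] = 4.0 * M_PI / 3.0 *
           (rout[i] * rout[i] * rout[i] - rin[i] * rin[i] * rin[i]);
  }
}

// Advance (u, v, V_E) by one step.  Returns clamped mass.  su/sv are
// optional extra sources (manufactured-solution forcing), constant over
// the step.
static double advance(std::vector<double> &u, std::vector<double> &v,
                      double &VE, const Params &p, double dr, double dt,
                      int reaction_order, int mask_rule, int include_reaction,
                      double u_bc,
                      const std::vector<double> &gfac,
                      const std::vector<double> &w,
                      const double *su, const double *sv) {
  int n = u.size();
  std::vector<double> DfU(n - 1), DfV(n - 1, p.DC);
  tumor_face_D(u, p, mask_rule, DfU);

  std::vector<double> Fu(n), Fv(n), u1(n), v1(n);
  double Q0 = 0.0;
  for (int i = 0; i < n; ++i) {
    Fu[i] = include_reaction ? f1(u[i], v[i], p) : 0.0;
    Fv[i] = include_reaction ? f2(u[i], v[i], p) : 0.0;
    if (su) Fu[i] += su[i];
    if (sv) Fv[i] += sv[i];
    Q0 += p.q * u[i] * v[i] * w[i];
  }
  cn_solve(u, DfU, gfac, w, dt, Fu, 1, u_bc, u1);
  cn_solve(v, DfV, gfac, w, dt, Fv, 0, 0.0, v1);

  if (reaction_order == 2) {
    std::vector<double> Fu2(n), Fv2(n);
    for (int i = 0; i < n; ++i) {
      double fu = include_reaction ? f1(u1[i], v1[i], p) : 0.0;
      double fv = include_reaction ? f2(u1[i], v1[i], p) : 0.0;
      if (su) fu += su[i];
      if (sv) fv += sv[i];
      Fu2[i] = 0.5 * (Fu[i] + fu);
      Fv2[i] = 0.5 * (Fv[i] + fv);
    }
    cn_solve(u, DfU, gfac, w, dt, Fu2, 1, u_bc, u1);
    cn_solve(v, DfV, gfac, w, dt, Fv2, 0, 0.0, v1);
  }

  double clamped = 0.0;
  double Q1 = 0.0;
  for (int i = 0; i < n; ++i) {
    if (u1[i] < 0.0) { clamped += -u1[i] * w[i]; u1[i] = 0.0; }
    if (v1[i] < 0.0) { clamped += -v1[i] * w[i]; v1[i] = 0.0; }
    Q1 += p.q * u1[i] * v1[i] * w[i];
  }
  double decay = std::exp(-p.m * dt);
  VE = decay * VE + 0.5 * dt * (decay * Q0 + Q1);
  if (VE < 0.0) VE = 0.0;
  u.swap(u1);
  v.swap(v1);
  return clamped;
}

// [[Rcpp::export]]
List cpp_cn_run(NumericVector u0, NumericVector v0, double VE0, double t0,
                double dr, double dt, int nsteps, List par, double u_detect,
                int record_every, int snapshot_every, int reaction_order,
                int mask_rule, double stop_tumor_below,
                double stop_radius_above, double margin_cm,
                int stop_on_margin) {
  int n = u0.size();
  Params p = make_params(par);
  std::vector<double> u(u0.begin(), u0.end()), v(v0.begin(), v0.end());
  std::vector<double> gfac, w, rin, rout;
  geometry(n, dr, gfac, w, rin, rout);
  double rmax = (n - 1) * dr;
  double VE = VE0, clamped = 0.0;
  int margin_node = std::max(0, (int)std::floor((rmax - margin_cm) / dr));

  std::vector<double> rec_t, rec_u, rec_v, rec_ve, rec_rd, rec_det, rec_cl;
  std::vector<double> snap_t;
  std::vector<std::vector<double>> snap_u, snap_v;
  int stop_code = 0, margin_hit = 0;
  int step = 0;

  auto record = [&](double t) {
    double tot_u = 0.0, tot_v = 0.0;
    for (int i = 0; i < n; ++i) { tot_u += u[i] * w[i]; tot_v += v[i] * w[i]; }
    double rd = detect_radius(u, dr, u_detect);
    rec_t.push_back(t);
    rec_u.push_back(tot_u);
    rec_v.push_back(tot_v);
    rec_ve.push_back(VE);
    rec_rd.push_back(rd);
    rec_det.push_back(cells_within(u, rin, rout, rd));
    rec_cl.push_back(clamped);
  };
  auto snapshot = [&](double t) {
    snap_t.push_back(t);
    snap_u.push_back(u);
    snap_v.push_back(v);
  };

  record(t0);
  if (snapshot_every > 0) snapshot(t0);

  for (step = 1; step <= nsteps; ++step) {
    clamped += advance(u, v, VE, p, dr, dt, reaction_order, mask_rule, 1, 0.0,
                       gfac, w, nullptr, nullptr);
    double t = t0 + step * dt;
    bool last = (step == nsteps);

    // per-step scalars for stopping rules
    double tot_u = 0.0;
    for (int i = 0; i < n; ++i) tot_u += u[i] * w[i];
    double rd = detect_radius(u, dr, u_detect);

    if (!margin_hit) {
      for (int i = margin_node; i < n; ++i)
        if (u[i] > 1.0) { margin_hit = 1; break; }
    }
    if (stop_tumor_below > 0.0 && tot_u < stop_tumor_below) stop_code = 1;
    if (stop_radius_above > 0.0 && rd >= stop_radius_above) stop_code = 2;
    if (stop_on_margin && margin_hit) stop_code = 3;

    if (stop_code != 0 || last || step % record_every == 0) record(t);
    if (snapshot_every > 0 && (stop_code != 0 || last ||
                               step % snapshot_every == 0)) snapshot(t);
    if (stop_code != 0) break;
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  int nr = rec_t.size();
  NumericMatrix series(nr, 7);
  colnames(series) = CharacterVector::create(
      "t", "tumor", "effector", "exhausted", "r_detect", "detectable",
      "clamped");
  for (int i = 0; i < nr; ++i) {
    series(i, 0) = rec_t[i]; series(i, 1) = rec_u[i];
    series(i, 2) = rec_v[i]; series(i, 3) = rec_ve[i];
    series(i, 4) = rec_rd[i]; series(i, 5) = rec_det[i];
    series(i, 6) = rec_cl[i];
  }

  List snaps = R_NilValue;
  if (snapshot_every > 0) {
    int ns = snap_t.size();
    NumericMatrix su_(n, ns), sv_(n, ns);
    for (int sidx = 0; sidx < ns; ++sidx)
      for (int i = 0; i < n; ++i) {
        su_(i, sidx) = snap_u[sidx][i];
        sv_(i, sidx) = snap_v[sidx][i];
      }
    snaps = List::create(_["t"] = NumericVector(snap_t.begin(), snap_t.end()),
                         _["u"] = su_, _["v"] = sv_);
  }

  return List::create(
      _["u"] = NumericVector(u.begin(), u.end()),
      _["v"] = NumericVector(v.begin(), v.end()),
      _["V_E"] = VE, _["t"] = rec_t[nr - 1], _["series"] = series,
      _["snapshots"] = snaps, _["stop_code"] = stop_code,
      _["margin_hit"] = margin_hit, _["clamped_mass"] = clamped,
      _["steps_taken"] = std::min(step, nsteps));
}

// Single step with optional manufactured sources and a Dirichlet value
// for u at the outer boundary; used by the MMS verification driver.
// [[Rcpp::export]]
List cpp_cn_step(NumericVector u0, NumericVector v0, double VE0, double dr,
                 double dt, List par, int reaction_order, int mask_rule,
                 int include_reaction, double u_bc,
                 Nullable<NumericVector> su_, Nullable<NumericVector> sv_) {
  int n = u0.size();
  Params p = make_params(par);
  std::vector<double> u(u0.begin(), u0.end()), v(v0.begin(), v0.end());
  std::vector<double> gfac, w, rin, rout;
  geometry(n, dr, gfac, w, rin, rout);
  double VE = VE0;
  const double *su = nullptr, *sv = nullptr;
  NumericVector suv, svv;
  if (su_.isNotNull()) { suv = su_.get(); su = REAL(suv); }
  if (sv_.isNotNull()) { svv = sv_.get(); sv = REAL(svv); }
  double clamped = advance(u, v, VE, p, dr, dt, reaction_order, mask_rule,
                           include_reaction, u_bc, gfac, w, su, sv);
  return List::create(_["u"] = NumericVector(u.begin(), u.end()),
                      _["v"] = NumericVector(v.begin(), v.end()),
                      _["V_E"] = VE, _["clamped_mass"] = clamped);
}
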