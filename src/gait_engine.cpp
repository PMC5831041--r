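// Event-driven core of the quasi-static hexapod gait model.
//
// The body is a rigid plate on six massless vertical springs whose root
// position and neutral length are commanded by one phase oscillator per leg.
// Between contact events all reduced phases advance uniformly, so the
// integration variable is cumulative phase advance; events (touchdown =
// upward zero crossing of a swing leg's hypothetical compression, liftoff =
// downward zero crossing of a stance leg's compression) are located by
// bracketing on a grid and bisection/secant refinement.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double TWO_PI_ = 6.283185307179586476925286766559;
static const double EV_TOL = 1e-10;   // event tolerance in phase units
static const double ROOT_TOL = 1e-13; // root refinement tolerance

struct Geom {
  double a, b, d, K, beta, s; // dimensionless body geometry
};

static Geom as_geom(const List& g) {
  Geom G;
  G.a = as<double>(g["a_star"]);
  G.b = as<double>(g["b_star"]);
  G.d = as<double>(g["d_star"]);
  G.K = as<double>(g["K_star"]);
  G.beta = as<double>(g["beta"]);
  G.s = as<double>(g["s_star"]);
  return G;
}

static inline double wrap(double x) {
  x -= TWO_PI_ * std::floor(x / TWO_PI_);
  if (x >= TWO_PI_) x -= TWO_PI_; // guard against rounding at the boundary
  if (x < 0) x = 0;
  return x;
}

// commanded neutral length and root offset for one leg
static inline void leg_kin(double eff, const Geom& g, double& L, double& dx) {
  double bp2 = 2.0 * g.beta * M_PI;
  if (eff < bp2) {
    L = 1.0;
    dx = g.s * (0.5 - eff / bp2);
  } else {
    double u = (eff - bp2) / (2.0 * (1.0 - g.beta));
    L = 1.0 - g.d * std::sin(u);
    dx = g.s * (-0.5 + u / M_PI);
  }
}

// Quasi-static equilibrium: linearized force balance and pitch/roll moment
// balance with the small-angle rotation matrix; returns hypothetical
// compressions for all six legs.  false = geometrically singular stance set.
static bool eq_solve(const double eff[6], const bool contact[6], const Geom& g,
                     double& pitch, double& roll, double& height, double dl[6]) {
  static const double XI[6] = {1, 0, -1, 1, 0, -1};
  double p[6], L[6], cc[6];
  for (int i = 0; i < 6; i++) {
    double Li, dxi;
    leg_kin(eff[i], g, Li, dxi);
    p[i] = XI[i] * g.a + dxi;
    L[i] = Li;
    cc[i] = (i < 3 ? g.b : -g.b);
  }
  int S[6], n = 0;
  for (int i = 0; i < 6; i++) if (contact[i]) S[n++] = i;
  if (n < 3) return false;

  // collinear feet => moments cannot be balanced
  double mx = 0, my = 0;
  for (int k = 0; k < n; k++) { mx += p[S[k]]; my += -cc[S[k]]; }
  mx /= n; my /= n;
  double sxx = 0, sxy = 0, syy = 0;
  for (int k = 0; k < n; k++) {
    double ddx = p[S[k]] - mx, ddy = -cc[S[k]] - my;
    sxx += ddx * ddx; sxy += ddx * ddy; syy += ddy * ddy;
  }
  double tr = sxx + syy, det2 = sxx * syy - sxy * sxy;
  double lmin = tr / 2 - std::sqrt(std::max(tr * tr / 4 - det2, 0.0));
  if (lmin < 1e-9 * std::max(tr, 1.0)) return false;

  double Sp = 0, Sc = 0, SL = 0, Spp = 0, Spc = 0, Scc = 0, SpL = 0, ScL = 0;
  for (int k = 0; k < n; k++) {
    int i = S[k];
    Sp += p[i]; Sc += cc[i]; SL += L[i];
    Spp += p[i] * p[i]; Spc += p[i] * cc[i]; Scc += cc[i] * cc[i];
    SpL += p[i] * L[i]; ScL += cc[i] * L[i];
  }
  double K = g.K, iK = 1.0 / K;
  // rows scaled by 1/K so entries are O(1)
  double A[3][3] = {{Sp, Sc, -(double)n},
                    {Spp - iK, Spc, -Sp},
                    {-Spc, -Scc + iK, Sc}};
  double bb[3] = {iK - SL, -SpL, ScL};
  double det = A[0][0] * (A[1][1] * A[2][2] - A[1][2] * A[2][1])
             - A[0][1] * (A[1][0] * A[2][2] - A[1][2] * A[2][0])
             + A[0][2] * (A[1][0] * A[2][1] - A[1][1] * A[2][0]);
  double scale = std::max(std::fabs(Spp) + std::fabs(Scc) + 1.0, 1.0);
  if (std::fabs(det) < 1e-12 * scale * scale * scale) return false;
  double x[3];
  for (int c = 0; c < 3; c++) {
    double M[3][3];
    for (int r = 0; r < 3; r++)
      for (int q = 0; q < 3; q++) M[r][q] = (q == c ? bb[r] : A[r][q]);
    double dc = M[0][0] * (M[1][1] * M[2][2] - M[1][2] * M[2][1])
              - M[0][1] * (M[1][0] * M[2][2] - M[1][2] * M[2][0])
              + M[0][2] * (M[1][0] * M[2][1] - M[1][1] * M[2][0]);
    x[c] = dc / det;
  }
  pitch = x[0]; roll = x[1]; height = x[2];
  for (int i = 0; i < 6; i++)
    dl[i] = p[i] * pitch + cc[i] * roll + L[i] - height;
  return true;
}

// compression of leg j at phase advance ds past the current state
static inline bool dl_at(const double phi3[3], const bool contact[6],
                         const Geom& g, double ds, double out[6]) {
  double eff[6];
  for (int i = 0; i < 3; i++) {
    eff[i] = wrap(phi3[i] + ds);
    eff[i + 3] = wrap(phi3[i] + M_PI + ds);
  }
  double pitch, roll, height;
  return eq_solve(eff, contact, g, pitch, roll, height, out);
}

// bisection + secant refinement of a single leg's compression zero
static double refine_root(const double phi3[3], const bool contact[6],
                          const Geom& g, int leg, double lo, double hi,
                          double flo, double fhi) {
  double tmp[6];
  for (int it = 0; it < 100 && (hi - lo) > ROOT_TOL; it++) {
    double mid;
    if (std::fabs(fhi - flo) > 1e-300) {
      mid = lo - flo * (hi - lo) / (fhi - flo); // secant proposal
      double lim = 0.1 * (hi - lo);
      if (mid < lo + lim || mid > hi - lim) mid = 0.5 * (lo + hi);
    } else mid = 0.5 * (lo + hi);
    if (!dl_at(phi3, contact, g, mid, tmp)) return 0.5 * (lo + hi);
    double fm = tmp[leg];
    if ((flo < 0 && fm < 0) || (flo > 0 && fm > 0)) { lo = mid; flo = fm; }
    else { hi = mid; fhi = fm; }
  }
  return 0.5 * (lo + hi);
}

// status: 0 ok, 1 stalled (fewer than 3 stance legs), 2 singular during
// event search, 3 event budget exhausted
// [[Rcpp::export(name = ".eng_simulate")]]
List eng_simulate(NumericVector phi3_in, LogicalVector contact_in, List geom,
                  int n_cycles, int record_leg = 2, int max_events = 100000) {
  Geom g = as_geom(geom);
  double bp2 = 2.0 * g.beta * M_PI;
  double phi3[3];
  bool contact[6];
  // a leg whose liftoff would leave the body statically unsupportable stays
  // adhered (spring force may pull) until the support set is solvable again
  bool pending[6] = {false, false, false, false, false, false};
  for (int i = 0; i < 3; i++) phi3[i] = wrap(phi3_in[i]);
  for (int i = 0; i < 6; i++) contact[i] = contact_in[i];

  std::vector<double> ev_sigma, ev_leg, ev_type, ev_phi, ev_reset;
  std::vector<double> sm_iter, sm_psi1, sm_psi2, sm_phi, sm_sigma;
  int n_td2 = 0, status = 3;
  double sigma = 0.0;
  double grid_dl[32][6];
  int toggles[6] = {0, 0, 0, 0, 0, 0};
  double toggle_sigma = -1.0;

  // shared touchdown processing (event log, Poincare sample, phase reset)
  auto do_touchdown = [&](int leg) {
    double eff_leg = wrap(phi3[leg % 3] + (leg >= 3 ? M_PI : 0.0));
    if (leg + 1 == record_leg) {
      sm_iter.push_back(n_td2);
      sm_psi1.push_back(wrap(phi3[1] - phi3[0]));
      sm_psi2.push_back(wrap(phi3[2] - phi3[1]));
      sm_phi.push_back(eff_leg);
      sm_sigma.push_back(sigma);
      n_td2++;
    }
    contact[leg] = true;
    double amt = (eff_leg >= bp2) ? (TWO_PI_ - eff_leg) / 2.0 : 0.0;
    int osc = leg % 3;
    phi3[osc] = wrap(phi3[osc] + amt);
    ev_sigma.push_back(sigma); ev_leg.push_back(leg + 1);
    ev_type.push_back(1); ev_phi.push_back(eff_leg); ev_reset.push_back(amt);
  };
  auto log_liftoff = [&](int leg) {
    contact[leg] = false;
    pending[leg] = false;
    ev_sigma.push_back(sigma); ev_leg.push_back(leg + 1);
    ev_type.push_back(2); ev_phi.push_back(NA_REAL); ev_reset.push_back(0.0);
  };
  auto solvable_without = [&](int leg) {
    bool save = contact[leg];
    contact[leg] = false;
    double eff_t[6], dl_t[6], a1, a2, a3;
    for (int i = 0; i < 3; i++) {
      eff_t[i] = phi3[i];
      eff_t[i + 3] = wrap(phi3[i] + M_PI);
    }
    bool ok = eq_solve(eff_t, contact, g, a1, a2, a3, dl_t);
    contact[leg] = save;
    return ok;
  };

  // Resolve the contact set at the current instant: lift legs whose springs
  // would pull (guarded by support solvability; otherwise they adhere) and
  // ground airborne feet pushed onto the floor by posture jumps.  Each leg
  // may toggle a bounded number of times per instant, which breaks the
  // chattering that pure complementarity can produce at degenerate states.
  auto resolve_instant = [&]() {
    if (sigma > toggle_sigma + 1e-12) {
      for (int i = 0; i < 6; i++) toggles[i] = 0;
      toggle_sigma = sigma;
    }
    for (int pass = 0; pass < 16; pass++) {
      double eff_t[6], dl0[6], dl1[6], a1, a2, a3;
      for (int i = 0; i < 3; i++) {
        eff_t[i] = phi3[i];
        eff_t[i + 3] = wrap(phi3[i] + M_PI);
      }
      if (!eq_solve(eff_t, contact, g, a1, a2, a3, dl0)) return false;
      if (!dl_at(phi3, contact, g, 1e-8, dl1)) return false;
      // removals first: most negative stretched spring
      int rm = -1; double rv = R_PosInf;
      for (int j = 0; j < 6; j++) {
        if (!contact[j] || toggles[j] >= 3) continue;
        bool cand = pending[j] || dl0[j] < -EV_TOL ||
                    (dl0[j] <= EV_TOL && dl1[j] < dl0[j]);
        if (cand && dl0[j] < rv) { rv = dl0[j]; rm = j; }
      }
      if (rm >= 0) {
        if (solvable_without(rm)) {
          log_liftoff(rm);
          toggles[rm]++;
          continue;
        }
        pending[rm] = true; // adhere; fall through to additions
      }
      // additions: airborne foot at/below ground and moving down
      int ad = -1; double av = -EV_TOL;
      for (int j = 0; j < 6; j++)
        if (!contact[j] && toggles[j] < 3 && dl0[j] >= av && dl1[j] > dl0[j]) {
          av = dl0[j]; ad = j;
        }
      if (ad >= 0) {
        do_touchdown(ad);
        toggles[ad]++;
        continue;
      }
      return true;
    }
    return true;
  };

  for (int it = 0; it < max_events; it++) {
    if (!resolve_instant()) { status = 2; break; }
    if (n_td2 >= n_cycles + 1) { status = 0; break; }
    int nS = 0;
    for (int i = 0; i < 6; i++) if (contact[i]) nS++;
    if (nS < 3) { status = 1; break; }
    double eff[6];
    for (int i = 0; i < 3; i++) {
      eff[i] = phi3[i];
      eff[i + 3] = wrap(phi3[i] + M_PI);
    }
    // window: no normal-stance leg may start unloading inside it
    double window = 0.35;
    for (int i = 0; i < 6; i++)
      if (contact[i] && eff[i] < bp2) {
        double m = bp2 - eff[i];
        if (m > 1e-12 && m < window) window = m;
      }
    int ng = (int)std::ceil(window / 0.04) + 1;
    if (ng < 3) ng = 3;
    if (ng > 24) ng = 24;
    bool grid_ok = true;
    for (int k = 0; k < ng; k++) {
      double ds = window * k / (ng - 1);
      if (!dl_at(phi3, contact, g, ds, grid_dl[k])) { grid_ok = false; break; }
    }
    if (!grid_ok) { status = 2; break; }

    // earliest interior zero crossing per leg
    double best_s = R_PosInf;
    int best_leg = -1, best_type = 0; // 1 touchdown, 2 liftoff
    for (int j = 0; j < 6; j++) {
      double s_j = R_PosInf;
      int t_j = 0;
      if (contact[j]) {
        if (pending[j]) continue; // adhered: release is handled above
        for (int k = 0; k + 1 < ng; k++)
          if (grid_dl[k][j] > 0 && grid_dl[k + 1][j] <= 0) {
            double lo = window * k / (ng - 1), hi = window * (k + 1) / (ng - 1);
            s_j = refine_root(phi3, contact, g, j, lo, hi,
                              grid_dl[k][j], grid_dl[k + 1][j]);
            t_j = 2;
            break;
          }
      } else {
        for (int k = 0; k + 1 < ng; k++)
          if (grid_dl[k][j] < 0 && grid_dl[k + 1][j] >= 0) {
            double lo = window * k / (ng - 1), hi = window * (k + 1) / (ng - 1);
            s_j = refine_root(phi3, contact, g, j, lo, hi,
                              grid_dl[k][j], grid_dl[k + 1][j]);
            t_j = 1;
            break;
          }
      }
      if (t_j == 0) continue;
      bool take = false;
      if (s_j < best_s - EV_TOL) take = true;
      else if (s_j <= best_s + EV_TOL && t_j == 2 && best_type == 1)
        take = true; // ties: liftoffs first; legs scanned in ascending order
      if (take) { best_s = s_j; best_leg = j; best_type = t_j; }
    }

    if (best_leg < 0) { // no event inside the window: advance to its end
      for (int i = 0; i < 3; i++) phi3[i] = wrap(phi3[i] + window);
      sigma += window;
      continue;
    }

    for (int i = 0; i < 3; i++) phi3[i] = wrap(phi3[i] + best_s);
    sigma += best_s;

    if (best_type == 2) { // liftoff (guarded; adhere if support would fail)
      if (solvable_without(best_leg)) log_liftoff(best_leg);
      else pending[best_leg] = true;
    } else {
      do_touchdown(best_leg);
      if (n_td2 >= n_cycles + 1) { status = 0; break; }
    }
  }

  int ne = ev_sigma.size(), nsmp = sm_iter.size();
  NumericMatrix events(ne, 5), samples(nsmp, 5);
  for (int k = 0; k < ne; k++) {
    events(k, 0) = ev_sigma[k]; events(k, 1) = ev_leg[k];
    events(k, 2) = ev_type[k];  events(k, 3) = ev_phi[k];
    events(k, 4) = ev_reset[k];
  }
  for (int k = 0; k < nsmp; k++) {
    samples(k, 0) = sm_iter[k]; samples(k, 1) = sm_psi1[k];
    samples(k, 2) = sm_psi2[k]; samples(k, 3) = sm_phi[k];
    samples(k, 4) = sm_sigma[k];
  }
  NumericVector phi_out(3);
  LogicalVector contact_out(6);
  for (int i = 0; i < 3; i++) phi_out[i] = phi3[i];
  for (int i = 0; i < 6; i++) contact_out[i] = contact[i];
  return List::create(_["events"] = events, _["samples"] = samples,
                      _["phi3"] = phi_out, _["contact"] = contact_out,
                      _["status"] = status);
}

// [[Rcpp::export(name = ".eng_equilibrium")]]
List eng_equilibrium(NumericVector eff_in, LogicalVector contact_in, List geom) {
  Geom g = as_geom(geom);
  double eff[6], dl[6], pitch, roll, height;
  bool contact[6];
  for (int i = 0; i < 6; i++) {
    eff[i] = wrap(eff_in[i]);
    contact[i] = contact_in[i];
  }
  bool ok = eq_solve(eff, contact, g, pitch, roll, height, dl);
  NumericVector dlv(6);
  for (int i = 0; i < 6; i++) dlv[i] = dl[i];
  return List::create(_["ok"] = ok, _["pitch"] = pitch, _["roll"] = roll,
                      _["height"] = height, _["dl"] = dlv);
}

// State on the leg-2 touchdown section for given relative phases: find the
// largest swing-branch phase x of oscillator 2 where leg 2's gap crosses
// zero upward, then back the whole state off along the flow so that contact
// flags are assigned away from branch boundaries.  Stance flags start from a
// generous phase test and are cleaned up by complementarity (drop legs whose
// compression is negative).
// [[Rcpp::export(name = ".eng_section")]]
List eng_section(double psi1, double psi2, List geom, double backoff = 0.02) {
  Geom g = as_geom(geom);
  double bp2 = 2.0 * g.beta * M_PI;
  double slack = std::min(0.04, 4.0 * (1.0 - g.beta) / (g.d * g.K));

  struct Local {
    Geom g; double psi1, psi2, bp2, slack, backoff;
    bool state(double x, double phi3[3], bool contact[6]) {
      phi3[0] = wrap(x - psi1); phi3[1] = wrap(x); phi3[2] = wrap(x + psi2);
      double eff[6];
      for (int i = 0; i < 3; i++) {
        eff[i] = phi3[i];
        eff[i + 3] = wrap(phi3[i] + M_PI);
      }
      // start from five-leg support and shed legs the ground cannot hold,
      // keeping the support set solvable (feet may adhere; see simulate)
      for (int i = 0; i < 6; i++) contact[i] = true;
      contact[1] = false;
      double dl[6], pitch, roll, height;
      if (!eq_solve(eff, contact, g, pitch, roll, height, dl)) return false;
      for (int rep = 0; rep < 6; rep++) {
        int worst = -1; double wv = -1e-12;
        for (int i = 0; i < 6; i++)
          if (contact[i] && dl[i] < wv) { wv = dl[i]; worst = i; }
        if (worst < 0) return true;
        contact[worst] = false;
        double dl2[6];
        if (!eq_solve(eff, contact, g, pitch, roll, height, dl2)) {
          contact[worst] = true; // adhered: removing it loses support
          return true;
        }
        for (int i = 0; i < 6; i++) dl[i] = dl2[i];
      }
      return true;
    }
    double gap2(double x, bool& ok) {
      double phi3[3]; bool contact[6];
      if (!state(x, phi3, contact)) { ok = false; return 0.0; }
      double eff[6], dl[6], pitch, roll, height;
      for (int i = 0; i < 3; i++) {
        eff[i] = phi3[i];
        eff[i + 3] = wrap(phi3[i] + M_PI);
      }
      if (!eq_solve(eff, contact, g, pitch, roll, height, dl)) {
        ok = false; return 0.0;
      }
      ok = true;
      return dl[1];
    }
  } L{g, psi1, psi2, bp2, slack, backoff};

  const int NX = 201;
  double xs[NX], gv[NX];
  bool okv[NX];
  for (int k = 0; k < NX; k++) {
    xs[k] = bp2 + 1e-9 + (TWO_PI_ - bp2 - 2e-9) * k / (NX - 1);
    gv[k] = L.gap2(xs[k], okv[k]);
  }
  double root = NA_REAL;
  for (int k = NX - 2; k >= 0; k--) {
    if (okv[k] && okv[k + 1] && gv[k] < 0 && gv[k + 1] >= 0) {
      double lo = xs[k], hi = xs[k + 1], flo = gv[k], fhi = gv[k + 1];
      for (int it = 0; it < 80 && (hi - lo) > 1e-12; it++) {
        double mid = 0.5 * (lo + hi);
        bool ok;
        double fm = L.gap2(mid, ok);
        if (!ok) break;
        if ((flo < 0) == (fm < 0)) { lo = mid; flo = fm; }
        else { hi = mid; fhi = fm; }
      }
      root = 0.5 * (lo + hi);
      break;
    }
  }
  if (!R_finite(root))
    return List::create(_["ok"] = false);
  double phi3[3]; bool contact[6];
  if (!L.state(root, phi3, contact))
    return List::create(_["ok"] = false);
  NumericVector phi_out(3);
  LogicalVector contact_out(6);
  for (int i = 0; i < 3; i++) phi_out[i] = wrap(phi3[i] - backoff);
  for (int i = 0; i < 6; i++) contact_out[i] = contact[i];
  return List::create(_["ok"] = true, _["phi3"] = phi_out,
                      _["contact"] = contact_out, _["x_section"] = root);
}
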