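// Core step loop of the CTL / target-cell co-culture simulator.
//
// All stochastic draws go through R's RNG (unif_rand / norm_rand) so that a
// single set.seed() at the R level makes whole runs bit-reproducible.
//
// Phase codes (targets): 1 = G1S, 2 = G2M, 3 = DEFENSE
// Mode  codes (CTL):     1 = SEARCH, 2 = ATTACK, 3 = DISABLED
// Event codes: 1 DEATH, 2 DIVISION, 3 DISABLE, 4 BOND, 5 UNBOND

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>

using namespace Rcpp;

static const int PH_G1S = 1, PH_G2M = 2, PH_DEF = 3;
static const int MD_SEARCH = 1, MD_ATTACK = 2, MD_DISABLED = 3;
static const int EV_DEATH = 1, EV_DIVISION = 2, EV_DISABLE = 3,
                 EV_BOND = 4, EV_UNBOND = 5;

struct World {
  double clock; // minutes
  // targets (parallel vectors)
  std::vector<int>    tid, tphase, tstored, tline;
  std::vector<double> tx, ty, tr, tmass, trem, tg1s, tg2m, tsurv;
  std::vector<char>   tdead;
  // CTL
  std::vector<int>    cid, cmode, cbond, cbstep, cki;
  std::vector<double> cx, cy, cr, ckf;
  // target-target adhesion bonds, by agent id
  std::vector<int>    ba, bb;
  std::vector<double> brest;

  size_t nt() const { return tx.size(); }
  size_t nc() const { return cx.size(); }

  // dense id -> target index lookup (-1 = absent), rebuilt on demand
  std::vector<int> tlook;
  void buildLookup() {
    int mx = 0;
    for (size_t i = 0; i < tid.size(); ++i) mx = std::max(mx, tid[i]);
    tlook.assign((size_t)mx + 1, -1);
    for (size_t i = 0; i < tid.size(); ++i) tlook[tid[i]] = (int)i;
  }
  int tindex(int id) const {
    if (id < 0 || (size_t)id >= tlook.size()) return -1;
    return tlook[id];
  }
};

struct Cfg {
  double dt, well_radius, k_spring, damping, k_rep, diffusion;
  double contact_tol, break_factor;
  double s_total, rd, pd_step;
  bool   per_target;            // disabling hazard per defending target in radius
  double g1s_mean, g1s_sd, g2m_mean, g2m_sd;
  double max_pop;
};

struct Events {
  bool on;
  std::vector<double> time;
  std::vector<int> type, id1, id2;
  void push(double t, int ty, int a, int b) {
    if (!on) return;
    time.push_back(t); type.push_back(ty); id1.push_back(a); id2.push_back(b);
  }
};

// ---------------------------------------------------------------------------
// uniform grid for neighbor queries

struct Grid {
  double cell, minx, miny;
  int nx, ny;
  std::vector<int> head, nxt;
  const std::vector<double> *px, *py;

  void build(const std::vector<double>& x, const std::vector<double>& y,
             double cellSize) {
    px = &x; py = &y;
    cell = cellSize > 0 ? cellSize : 1.0;
    size_t n = x.size();
    if (n == 0) { nx = ny = 1; minx = miny = 0; head.assign(1, -1); nxt.clear(); return; }
    double maxx = x[0], maxy = y[0];
    minx = x[0]; miny = y[0];
    for (size_t i = 1; i < n; ++i) {
      minx = std::min(minx, x[i]); maxx = std::max(maxx, x[i]);
      miny = std::min(miny, y[i]); maxy = std::max(maxy, y[i]);
    }
    nx = (int)((maxx - minx) / cell) + 1;
    ny = (int)((maxy - miny) / cell) + 1;
    head.assign((size_t)nx * ny, -1);
    nxt.assign(n, -1);
    for (size_t i = 0; i < n; ++i) {
      int cxi = (int)(((*px)[i] - minx) / cell);
      int cyi = (int)(((*py)[i] - miny) / cell);
      int c = cyi * nx + cxi;
      nxt[i] = head[c];
      head[c] = (int)i;
    }
  }

  // count points within `radius` of (x, y): cells fully inside the disc
  // contribute their occupancy without per-point distance checks
  int countWithin(double x, double y, double radius) const {
    if (head.empty()) return 0;
    int c0 = (int)std::floor((x - radius - minx) / cell);
    int c1 = (int)std::floor((x + radius - minx) / cell);
    int r0 = (int)std::floor((y - radius - miny) / cell);
    int r1 = (int)std::floor((y + radius - miny) / cell);
    c0 = std::max(c0, 0); r0 = std::max(r0, 0);
    c1 = std::min(c1, nx - 1); r1 = std::min(r1, ny - 1);
    double r2 = radius * radius;
    int total = 0;
    for (int r = r0; r <= r1; ++r) {
      double ylo = miny + r * cell, yhi = ylo + cell;
      double dy = std::max({ylo - y, y - yhi, 0.0});
      double dyf = std::max(std::abs(y - ylo), std::abs(yhi - y));
      for (int c = c0; c <= c1; ++c) {
        int h = head[r * nx + c];
        if (h == -1) continue;
        double xlo = minx + c * cell, xhi = xlo + cell;
        double dx = std::max({xlo - x, x - xhi, 0.0});
        if (dx * dx + dy * dy > r2) continue; // cell entirely outside
        double dxf = std::max(std::abs(x - xlo), std::abs(xhi - x));
        if (dxf * dxf + dyf * dyf <= r2) { // cell entirely inside
          for (int j = h; j != -1; j = nxt[j]) ++total;
        } else {
          for (int j = h; j != -1; j = nxt[j]) {
            double ddx = (*px)[j] - x, ddy = (*py)[j] - y;
            if (ddx * ddx + ddy * ddy <= r2) ++total;
          }
        }
      }
    }
    return total;
  }

  // call f(j) for every point j in cells intersecting the disc of given radius
  template <typename F>
  void forCandidates(double x, double y, double radius, F f) const {
    if (head.empty()) return;
    int c0 = (int)std::floor((x - radius - minx) / cell);
    int c1 = (int)std::floor((x + radius - minx) / cell);
    int r0 = (int)std::floor((y - radius - miny) / cell);
    int r1 = (int)std::floor((y + radius - miny) / cell);
    c0 = std::max(c0, 0); r0 = std::max(r0, 0);
    c1 = std::min(c1, nx - 1); r1 = std::min(r1, ny - 1);
    for (int r = r0; r <= r1; ++r)
      for (int c = c0; c <= c1; ++c)
        for (int j = head[r * nx + c]; j != -1; j = nxt[j]) f(j);
  }
};

// ---------------------------------------------------------------------------
// conversions R <-> World

static World worldFromList(const List& w) {
  World W;
  W.clock = as<double>(w["clock"]);
  List tg = w["targets"], ct = w["ctls"], bd = w["bonds"];
  IntegerVector id = tg["id"], ph = tg["phase"], st = tg["stored_phase"], ln = tg["line"];
  NumericVector x = tg["x"], y = tg["y"], r = tg["radius"], m = tg["mass"],
                rem = tg["phase_remaining"], g1 = tg["g1s_dur"], g2 = tg["g2m_dur"],
                sv = tg["survival_remaining"];
  size_t nt = id.size();
  W.tid.assign(id.begin(), id.end());
  W.tphase.assign(ph.begin(), ph.end());
  W.tstored.assign(st.begin(), st.end());
  W.tline.assign(ln.begin(), ln.end());
  W.tx.assign(x.begin(), x.end()); W.ty.assign(y.begin(), y.end());
  W.tr.assign(r.begin(), r.end()); W.tmass.assign(m.begin(), m.end());
  W.trem.assign(rem.begin(), rem.end());
  W.tg1s.assign(g1.begin(), g1.end()); W.tg2m.assign(g2.begin(), g2.end());
  W.tsurv.assign(sv.begin(), sv.end());
  W.tdead.assign(nt, 0);

  IntegerVector ci = ct["id"], cm = ct["mode"], cb = ct["bonded_target"],
                cs = ct["bond_step"], ck = ct["kill_int"];
  NumericVector ccx = ct["x"], ccy = ct["y"], ccr = ct["radius"], ckf = ct["kill_frac"];
  W.cid.assign(ci.begin(), ci.end());
  W.cmode.assign(cm.begin(), cm.end());
  W.cbond.assign(cb.begin(), cb.end());
  W.cbstep.assign(cs.begin(), cs.end());
  W.cki.assign(ck.begin(), ck.end());
  W.cx.assign(ccx.begin(), ccx.end()); W.cy.assign(ccy.begin(), ccy.end());
  W.cr.assign(ccr.begin(), ccr.end()); W.ckf.assign(ckf.begin(), ckf.end());

  IntegerVector a = bd["a"], b = bd["b"];
  NumericVector rl = bd["rest_length"];
  W.ba.assign(a.begin(), a.end()); W.bb.assign(b.begin(), b.end());
  W.brest.assign(rl.begin(), rl.end());
  return W;
}

static List worldToList(const World& W) {
  List tg = List::create(
    _["id"] = IntegerVector(W.tid.begin(), W.tid.end()),
    _["x"] = NumericVector(W.tx.begin(), W.tx.end()),
    _["y"] = NumericVector(W.ty.begin(), W.ty.end()),
    _["radius"] = NumericVector(W.tr.begin(), W.tr.end()),
    _["mass"] = NumericVector(W.tmass.begin(), W.tmass.end()),
    _["phase"] = IntegerVector(W.tphase.begin(), W.tphase.end()),
    _["stored_phase"] = IntegerVector(W.tstored.begin(), W.tstored.end()),
    _["phase_remaining"] = NumericVector(W.trem.begin(), W.trem.end()),
    _["g1s_dur"] = NumericVector(W.tg1s.begin(), W.tg1s.end()),
    _["g2m_dur"] = NumericVector(W.tg2m.begin(), W.tg2m.end()),
    _["survival_remaining"] = NumericVector(W.tsurv.begin(), W.tsurv.end()),
    _["line"] = IntegerVector(W.tline.begin(), W.tline.end()));
  List ct = List::create(
    _["id"] = IntegerVector(W.cid.begin(), W.cid.end()),
    _["x"] = NumericVector(W.cx.begin(), W.cx.end()),
    _["y"] = NumericVector(W.cy.begin(), W.cy.end()),
    _["radius"] = NumericVector(W.cr.begin(), W.cr.end()),
    _["mode"] = IntegerVector(W.cmode.begin(), W.cmode.end()),
    _["kill_frac"] = NumericVector(W.ckf.begin(), W.ckf.end()),
    _["kill_int"] = IntegerVector(W.cki.begin(), W.cki.end()),
    _["bonded_target"] = IntegerVector(W.cbond.begin(), W.cbond.end()),
    _["bond_step"] = IntegerVector(W.cbstep.begin(), W.cbstep.end()));
  List bd = List::create(
    _["a"] = IntegerVector(W.ba.begin(), W.ba.end()),
    _["b"] = IntegerVector(W.bb.begin(), W.bb.end()),
    _["rest_length"] = NumericVector(W.brest.begin(), W.brest.end()));
  return List::create(_["clock"] = W.clock, _["targets"] = tg,
                      _["ctls"] = ct, _["bonds"] = bd);
}

static Cfg cfgFromList(const List& c) {
  Cfg f;
  f.dt = as<double>(c["dt"]);
  f.well_radius = as<double>(c["well_radius"]);
  f.k_spring = as<double>(c["k_spring"]);
  f.damping = as<double>(c["damping"]);
  f.k_rep = as<double>(c["k_rep"]);
  f.diffusion = as<double>(c["diffusion"]);
  f.contact_tol = as<double>(c["contact_tol"]);
  f.break_factor = as<double>(c["break_factor"]);
  f.s_total = as<double>(c["s_total"]);
  f.rd = as<double>(c["rd"]);
  f.pd_step = as<double>(c["pd_step"]);
  f.per_target = as<bool>(c["per_target"]);
  f.g1s_mean = as<double>(c["g1s_mean"]);
  f.g1s_sd = as<double>(c["g1s_sd"]);
  f.g2m_mean = as<double>(c["g2m_mean"]);
  f.g2m_sd = as<double>(c["g2m_sd"]);
  f.max_pop = as<double>(c["max_pop"]);
  return f;
}

// truncated-at-zero normal draw: resample up to 100 times, then clamp
static double truncNormal(double mean, double sd) {
  if (sd <= 0) return mean;
  for (int i = 0; i < 100; ++i) {
    double v = mean + sd * norm_rand();
    if (v > 0) return v;
  }
  return 0.01 * mean;
}

// ---------------------------------------------------------------------------
// mechanics: one overdamped Euler step (forces -> velocity via damping)

static void mechStep(World& W, const Cfg& cfg, Events& ev, int step) {
  size_t nt = W.nt(), nc = W.nc(), n = nt + nc;
  if (n == 0) { return; }
  std::vector<double> px(n), py(n), pr(n), fx(n, 0.0), fy(n, 0.0);
  for (size_t i = 0; i < nt; ++i) { px[i] = W.tx[i]; py[i] = W.ty[i]; pr[i] = W.tr[i]; }
  for (size_t i = 0; i < nc; ++i) { px[nt + i] = W.cx[i]; py[nt + i] = W.cy[i]; pr[nt + i] = W.cr[i]; }

  double rmax = 0;
  for (size_t i = 0; i < n; ++i) rmax = std::max(rmax, pr[i]);

  // soft repulsion between every overlapping pair (bonded or not)
  Grid g;
  g.build(px, py, 2.0 * rmax * (1.0 + cfg.contact_tol));
  for (size_t i = 0; i < n; ++i) {
    g.forCandidates(px[i], py[i], pr[i] + rmax, [&](int j) {
      if ((size_t)j <= i) return;
      double dx = px[j] - px[i], dy = py[j] - py[i];
      double sumr = pr[i] + pr[j];
      double d2 = dx * dx + dy * dy;
      if (d2 >= sumr * sumr) return;
      double d = std::sqrt(d2);
      double ux, uy;
      if (d < 1e-9) { double a = 2.0 * M_PI * unif_rand(); ux = std::cos(a); uy = std::sin(a); d = 1e-9; }
      else { ux = dx / d; uy = dy / d; }
      double fmag = cfg.k_rep * (sumr - d); // push apart
      fx[i] -= fmag * ux; fy[i] -= fmag * uy;
      fx[j] += fmag * ux; fy[j] += fmag * uy;
    });
  }

  W.buildLookup();

  // springs along target-target bonds (break if overstretched)
  std::vector<size_t> dropBonds;
  for (size_t b = 0; b < W.ba.size(); ++b) {
    int ia = W.tindex(W.ba[b]), ib = W.tindex(W.bb[b]);
    if (ia < 0 || ib < 0) { dropBonds.push_back(b); continue; }
    size_t i = (size_t)ia, j = (size_t)ib;
    double dx = px[j] - px[i], dy = py[j] - py[i];
    double d = std::sqrt(dx * dx + dy * dy);
    if (d > cfg.break_factor * W.brest[b]) {
      dropBonds.push_back(b);
      ev.push(W.clock, EV_UNBOND, W.ba[b], W.bb[b]);
      continue;
    }
    if (d < 1e-9) continue;
    double fmag = cfg.k_spring * (d - W.brest[b]); // attractive when stretched
    double ux = dx / d, uy = dy / d;
    fx[i] += fmag * ux; fy[i] += fmag * uy;
    fx[j] -= fmag * ux; fy[j] -= fmag * uy;
  }
  for (size_t k = dropBonds.size(); k-- > 0;) {
    size_t b = dropBonds[k];
    W.ba.erase(W.ba.begin() + b); W.bb.erase(W.bb.begin() + b);
    W.brest.erase(W.brest.begin() + b);
  }

  // springs along CTL-target attack bonds
  for (size_t i = 0; i < nc; ++i) {
    if (W.cbond[i] == 0) continue;
    int it = W.tindex(W.cbond[i]);
    if (it < 0) { W.cbond[i] = 0; if (W.cmode[i] == MD_ATTACK) W.cmode[i] = MD_SEARCH; continue; }
    size_t tj = (size_t)it, ci = nt + i;
    double rest = W.cr[i] + W.tr[tj];
    double dx = px[tj] - px[ci], dy = py[tj] - py[ci];
    double d = std::sqrt(dx * dx + dy * dy);
    if (d > cfg.break_factor * rest) { // mechanical contact loss
      ev.push(W.clock, EV_UNBOND, W.cid[i], W.cbond[i]);
      W.cbond[i] = 0;
      if (W.cmode[i] == MD_ATTACK) W.cmode[i] = MD_SEARCH;
      continue;
    }
    if (d < 1e-9) continue;
    double fmag = cfg.k_spring * (d - rest);
    double ux = dx / d, uy = dy / d;
    fx[ci] += fmag * ux; fy[ci] += fmag * uy;
    fx[tj] -= fmag * ux; fy[tj] -= fmag * uy;
  }

  // integrate: v = F / damping; Brownian displacement for SEARCH/DISABLED CTL
  double bsd = std::sqrt(2.0 * cfg.diffusion * cfg.dt);
  double scale = cfg.dt / cfg.damping;
  for (size_t i = 0; i < n; ++i) {
    double nxp = px[i] + fx[i] * scale;
    double nyp = py[i] + fy[i] * scale;
    if (i >= nt) {
      int m = W.cmode[i - nt];
      if ((m == MD_SEARCH || m == MD_DISABLED) && cfg.diffusion > 0) {
        nxp += bsd * norm_rand();
        nyp += bsd * norm_rand();
      }
    }
    if (!R_finite(nxp) || !R_finite(nyp)) {
      int id = i < nt ? W.tid[i] : W.cid[i - nt];
      stop("numerical instability: non-finite position for agent id %d", id);
    }
    // radial clamp at the well wall
    double rr = std::sqrt(nxp * nxp + nyp * nyp);
    double lim = cfg.well_radius - pr[i];
    if (lim < 0) lim = 0;
    if (rr > lim && rr > 0) { nxp *= lim / rr; nyp *= lim / rr; }
    if (i < nt) { W.tx[i] = nxp; W.ty[i] = nyp; }
    else { W.cx[i - nt] = nxp; W.cy[i - nt] = nyp; }
  }
  (void)step;
}

// maximum pairwise overlap as a fraction of summed radii
static double maxOverlapFrac(const World& W) {
  size_t nt = W.nt(), nc = W.nc(), n = nt + nc;
  if (n < 2) return 0.0;
  std::vector<double> px(n), py(n), pr(n);
  for (size_t i = 0; i < nt; ++i) { px[i] = W.tx[i]; py[i] = W.ty[i]; pr[i] = W.tr[i]; }
  for (size_t i = 0; i < nc; ++i) { px[nt + i] = W.cx[i]; py[nt + i] = W.cy[i]; pr[nt + i] = W.cr[i]; }
  double rmax = 0;
  for (size_t i = 0; i < n; ++i) rmax = std::max(rmax, pr[i]);
  Grid g; g.build(px, py, 2.0 * rmax);
  double worst = 0.0;
  for (size_t i = 0; i < n; ++i) {
    g.forCandidates(px[i], py[i], pr[i] + rmax, [&](int j) {
      if ((size_t)j <= i) return;
      double dx = px[j] - px[i], dy = py[j] - py[i];
      double sumr = pr[i] + pr[j];
      double d = std::sqrt(dx * dx + dy * dy);
      if (d < sumr) worst = std::max(worst, (sumr - d) / sumr);
    });
  }
  return worst;
}

// ---------------------------------------------------------------------------
// biology phases

// phase 1: contact detection, adhesion bond formation
static void bondPhase(World& W, const Cfg& cfg, Events& ev, int step) {
  size_t nt = W.nt(), nc = W.nc();
  if (nt == 0) return;

  std::unordered_set<long long> tbond;
  tbond.reserve(W.ba.size() * 2 + 1);
  for (size_t b = 0; b < W.ba.size(); ++b) {
    long long lo = std::min(W.ba[b], W.bb[b]), hi = std::max(W.ba[b], W.bb[b]);
    tbond.insert(lo * 10000000LL + hi);
  }

  double rmax = 0;
  for (size_t i = 0; i < nt; ++i) rmax = std::max(rmax, W.tr[i]);
  Grid g; g.build(W.tx, W.ty, 2.0 * rmax * (1.0 + cfg.contact_tol));

  // target-target adhesion on contact
  for (size_t i = 0; i < nt; ++i) {
    g.forCandidates(W.tx[i], W.ty[i], (W.tr[i] + rmax) * (1.0 + cfg.contact_tol), [&](int j) {
      if ((size_t)j <= i) return;
      double dx = W.tx[j] - W.tx[i], dy = W.ty[j] - W.ty[i];
      double lim = (W.tr[i] + W.tr[j]) * (1.0 + cfg.contact_tol);
      if (dx * dx + dy * dy > lim * lim) return;
      long long lo = std::min(W.tid[i], W.tid[j]), hi = std::max(W.tid[i], W.tid[j]);
      long long key = lo * 10000000LL + hi;
      if (tbond.count(key)) return;
      tbond.insert(key);
      W.ba.push_back(W.tid[i]); W.bb.push_back(W.tid[j]);
      W.brest.push_back(W.tr[i] + W.tr[j]);
      ev.push(W.clock, EV_BOND, (int)lo, (int)hi);
    });
  }

  // searching CTL adhere to the nearest contacting target and switch to ATTACK
  for (size_t i = 0; i < nc; ++i) {
    if (W.cmode[i] != MD_SEARCH) continue;
    int best = -1; double bestd = R_PosInf;
    g.forCandidates(W.cx[i], W.cy[i], (W.cr[i] + rmax) * (1.0 + cfg.contact_tol), [&](int j) {
      double dx = W.tx[j] - W.cx[i], dy = W.ty[j] - W.cy[i];
      double d = std::sqrt(dx * dx + dy * dy);
      double lim = (W.cr[i] + W.tr[j]) * (1.0 + cfg.contact_tol);
      if (d > lim) return;
      if (d < bestd || (d == bestd && best >= 0 && W.tid[j] < W.tid[best])) { bestd = d; best = j; }
    });
    if (best >= 0) {
      W.cbond[i] = W.tid[best];
      W.cbstep[i] = step;
      W.cmode[i] = MD_ATTACK;
      ev.push(W.clock, EV_BOND, W.cid[i], W.tid[best]);
    }
  }
}

// phase 2: target state machine (defense, survival depletion, death, cycling,
// division). Attacker counts are a frozen snapshot taken at entry.
static void targetPhase(World& W, const Cfg& cfg, Events& ev,
                        long long& cumDeaths, long long& cumDivs, int& nextTid) {
  size_t nt0 = W.nt(), nc = W.nc();
  if (nt0 == 0) return;

  W.buildLookup();
  std::vector<int> natt(nt0, 0);
  for (size_t i = 0; i < nc; ++i) {
    if (W.cmode[i] == MD_ATTACK && W.cbond[i] != 0) {
      int it = W.tindex(W.cbond[i]);
      if (it >= 0) natt[it]++;
    }
  }

  for (size_t i = 0; i < nt0; ++i) {
    if (W.tdead[i]) continue;
    int k = natt[i];
    if (k > 0) {
      if (W.tphase[i] != PH_DEF) { W.tstored[i] = W.tphase[i]; W.tphase[i] = PH_DEF; }
      W.tsurv[i] -= (double)k * cfg.dt;
      if (W.tsurv[i] <= 1e-9) {
        W.tsurv[i] = 0.0;
        W.tdead[i] = 1;
        ++cumDeaths;
        ev.push(W.clock + cfg.dt, EV_DEATH, W.tid[i], k);
        // credit: fractional 1/k to every current attacker; one integer credit
        // to the longest-attached attacker (earliest bond step, lowest id ties)
        int besti = -1;
        for (size_t c = 0; c < nc; ++c) {
          if (W.cmode[c] == MD_ATTACK && W.cbond[c] == W.tid[i]) {
            W.ckf[c] += 1.0 / (double)k;
            if (besti < 0 || W.cbstep[c] < W.cbstep[besti] ||
                (W.cbstep[c] == W.cbstep[besti] && W.cid[c] < W.cid[besti]))
              besti = (int)c;
          }
        }
        if (besti >= 0) W.cki[besti] += 1;
      }
    } else {
      if (W.tphase[i] == PH_DEF) W.tphase[i] = W.tstored[i]; // cycle timer frozen, resumes
      // cycling
      W.trem[i] -= cfg.dt;
      if (W.tphase[i] == PH_G1S) {
        if (W.trem[i] <= 0) { W.tphase[i] = PH_G2M; W.trem[i] += W.tg2m[i]; }
      }
      if (W.tphase[i] == PH_G2M) {
        double prog = (W.tg2m[i] - std::max(W.trem[i], 0.0)) / W.tg2m[i];
        W.tmass[i] = std::min(2.0, 1.0 + prog);
        if (W.trem[i] <= 0) {
          // division: reset mother, create daughter adjacent at 2*radius
          double carry = W.trem[i];
          W.tg1s[i] = truncNormal(cfg.g1s_mean, cfg.g1s_sd);
          W.tg2m[i] = truncNormal(cfg.g2m_mean, cfg.g2m_sd);
          W.tphase[i] = PH_G1S;
          W.trem[i] = W.tg1s[i] + carry;
          if (W.trem[i] <= 0) W.trem[i] = 0.01 * W.tg1s[i];
          W.tmass[i] = 1.0;
          double ang = 2.0 * M_PI * unif_rand();
          double dx = W.tx[i] + 2.0 * W.tr[i] * std::cos(ang);
          double dy = W.ty[i] + 2.0 * W.tr[i] * std::sin(ang);
          double rr = std::sqrt(dx * dx + dy * dy);
          double lim = cfg.well_radius - W.tr[i];
          if (rr > lim && rr > 0) { dx *= lim / rr; dy *= lim / rr; }
          int did = nextTid++;
          W.tid.push_back(did);
          W.tphase.push_back(PH_G1S);
          W.tstored.push_back(PH_G1S);
          W.tline.push_back(W.tline[i]);
          W.tx.push_back(dx); W.ty.push_back(dy);
          W.tr.push_back(W.tr[i]);
          W.tmass.push_back(1.0);
          double dg1 = truncNormal(cfg.g1s_mean, cfg.g1s_sd);
          W.trem.push_back(dg1);
          W.tg1s.push_back(dg1);
          W.tg2m.push_back(truncNormal(cfg.g2m_mean, cfg.g2m_sd));
          W.tsurv.push_back(cfg.s_total);
          W.tdead.push_back(0);
          ++cumDivs;
          ev.push(W.clock + cfg.dt, EV_DIVISION, W.tid[i], did);
        }
      }
    }
  }
}

// phase 3: CTL state machine (bond release on target death, probabilistic
// inactivation within R_d of defending targets)
static void ctlPhase(World& W, const Cfg& cfg, Events& ev, long long& cumDisabled) {
  size_t nt = W.nt(), nc = W.nc();

  W.buildLookup(); // includes dead-marked targets until compaction

  // defending, still-alive targets
  std::vector<double> dxv, dyv;
  for (size_t i = 0; i < nt; ++i)
    if (!W.tdead[i] && W.tphase[i] == PH_DEF) { dxv.push_back(W.tx[i]); dyv.push_back(W.ty[i]); }

  Grid g;
  bool anyDef = !dxv.empty();
  if (anyDef && cfg.pd_step > 0) g.build(dxv, dyv, std::max(cfg.rd / 3.0, 1.0));

  double rd2 = cfg.rd * cfg.rd;
  for (size_t i = 0; i < nc; ++i) {
    if (W.cmode[i] == MD_DISABLED) continue;
    // release bond on target death (the kill was credited in targetPhase)
    if (W.cbond[i] != 0) {
      int ti = W.tindex(W.cbond[i]);
      if (ti < 0 || W.tdead[ti]) { W.cbond[i] = 0; W.cmode[i] = MD_SEARCH; }
    }
    if (!anyDef || cfg.pd_step <= 0) continue;
    int m = 0;
    if (cfg.per_target) {
      m = g.countWithin(W.cx[i], W.cy[i], cfg.rd);
    } else {
      // per-CTL draw: only need existence of one defending target in radius
      bool found = false;
      g.forCandidates(W.cx[i], W.cy[i], cfg.rd, [&](int j) {
        if (found) return;
        double ddx = dxv[j] - W.cx[i], ddy = dyv[j] - W.cy[i];
        if (ddx * ddx + ddy * ddy <= rd2) found = true;
      });
      m = found ? 1 : 0;
    }
    if (m > 0) {
      double p = cfg.per_target ? 1.0 - std::pow(1.0 - cfg.pd_step, (double)m)
                                : cfg.pd_step;
      if (unif_rand() < p) {
        if (W.cbond[i] != 0) ev.push(W.clock + cfg.dt, EV_UNBOND, W.cid[i], W.cbond[i]);
        W.cbond[i] = 0;
        W.cmode[i] = MD_DISABLED; // absorbing
        ++cumDisabled;
        ev.push(W.clock + cfg.dt, EV_DISABLE, W.cid[i], NA_INTEGER);
      }
    }
  }
}

// remove dead targets and their bonds
static void compact(World& W) {
  size_t nt = W.nt();
  bool any = false;
  for (size_t i = 0; i < nt; ++i) if (W.tdead[i]) { any = true; break; }
  if (!any) return;
  std::unordered_set<int> dead;
  size_t w = 0;
  for (size_t i = 0; i < nt; ++i) {
    if (W.tdead[i]) { dead.insert(W.tid[i]); continue; }
    if (w != i) {
      W.tid[w] = W.tid[i]; W.tphase[w] = W.tphase[i]; W.tstored[w] = W.tstored[i];
      W.tline[w] = W.tline[i]; W.tx[w] = W.tx[i]; W.ty[w] = W.ty[i];
      W.tr[w] = W.tr[i]; W.tmass[w] = W.tmass[i]; W.trem[w] = W.trem[i];
      W.tg1s[w] = W.tg1s[i]; W.tg2m[w] = W.tg2m[i]; W.tsurv[w] = W.tsurv[i];
    }
    ++w;
  }
  W.tid.resize(w); W.tphase.resize(w); W.tstored.resize(w); W.tline.resize(w);
  W.tx.resize(w); W.ty.resize(w); W.tr.resize(w); W.tmass.resize(w);
  W.trem.resize(w); W.tg1s.resize(w); W.tg2m.resize(w); W.tsurv.resize(w);
  W.tdead.assign(w, 0);
  size_t b = 0;
  for (size_t i = 0; i < W.ba.size(); ++i) {
    if (dead.count(W.ba[i]) || dead.count(W.bb[i])) continue;
    W.ba[b] = W.ba[i]; W.bb[b] = W.bb[i]; W.brest[b] = W.brest[i];
    ++b;
  }
  W.ba.resize(b); W.bb.resize(b); W.brest.resize(b);
}

// ---------------------------------------------------------------------------
// main entry: advance the world n_steps, recording population series

// [[Rcpp::export]]
List cpp_run(List world, List cfg_list, int n_steps, int record_every,
             bool mechanics_only, bool record_events,
             int step0, double cum_deaths0, double cum_divs0, double cum_disabled0,
             int next_target_id) {
  World W = worldFromList(world);
  Cfg cfg = cfgFromList(cfg_list);
  Events ev; ev.on = record_events;

  long long cumDeaths = (long long)cum_deaths0;
  long long cumDivs = (long long)cum_divs0;
  long long cumDisabled = (long long)cum_disabled0;
  int nextTid = next_target_id;

  std::vector<double> recT;
  std::vector<double> recLive, recDeaths, recDivs, recSearch, recAttack, recDisabled;
  bool escaped = false;

  for (int s = 0; s < n_steps; ++s) {
    int gstep = step0 + s + 1;
    if (!mechanics_only) {
      bondPhase(W, cfg, ev, gstep);
      targetPhase(W, cfg, ev, cumDeaths, cumDivs, nextTid);
      ctlPhase(W, cfg, ev, cumDisabled);
    }
    mechStep(W, cfg, ev, gstep);
    if (!mechanics_only) compact(W);
    W.clock += cfg.dt;
    if ((double)W.nt() > cfg.max_pop) { escaped = true; }
    bool doRec = (record_every > 0 && gstep % record_every == 0);
    if (doRec || escaped || s == n_steps - 1) {
      if (doRec || escaped || s == n_steps - 1) {
        // always record the final/escape step; duplicates removed in R
        int nS = 0, nA = 0, nD = 0;
        for (size_t i = 0; i < W.nc(); ++i) {
          if (W.cmode[i] == MD_SEARCH) ++nS;
          else if (W.cmode[i] == MD_ATTACK) ++nA;
          else ++nD;
        }
        recT.push_back(W.clock);
        recLive.push_back((double)W.nt());
        recDeaths.push_back((double)cumDeaths);
        recDivs.push_back((double)cumDivs);
        recSearch.push_back((double)nS);
        recAttack.push_back((double)nA);
        recDisabled.push_back((double)nD);
      }
    }
    if (escaped) break;
  }

  List series = List::create(
    _["time_min"] = NumericVector(recT.begin(), recT.end()),
    _["live_targets"] = NumericVector(recLive.begin(), recLive.end()),
    _["cum_deaths"] = NumericVector(recDeaths.begin(), recDeaths.end()),
    _["cum_divisions"] = NumericVector(recDivs.begin(), recDivs.end()),
    _["n_search"] = NumericVector(recSearch.begin(), recSearch.end()),
    _["n_attack"] = NumericVector(recAttack.begin(), recAttack.end()),
    _["n_disabled"] = NumericVector(recDisabled.begin(), recDisabled.end()));

  List events = List::create(
    _["time_min"] = NumericVector(ev.time.begin(), ev.time.end()),
    _["type"] = IntegerVector(ev.type.begin(), ev.type.end()),
    _["id1"] = IntegerVector(ev.id1.begin(), ev.id1.end()),
    _["id2"] = IntegerVector(ev.id2.begin(), ev.id2.end()));

  return List::create(
    _["world"] = worldToList(W),
    _["series"] = series,
    _["events"] = events,
    _["cum_deaths"] = (double)cumDeaths,
    _["cum_divisions"] = (double)cumDivs,
    _["cum_disabled"] = (double)cumDisabled,
    _["next_target_id"] = nextTid,
    _["escaped"] = escaped);
}

// relax overlaps by repeated force-only steps (no noise, no biology);
// used for centrifugation-style initial packing
// [[Rcpp::export]]
List cpp_relax(List world, List cfg_list, double tol_frac, int max_iter) {
  World W = worldFromList(world);
  Cfg cfg = cfgFromList(cfg_list);
  cfg.diffusion = 0.0; // deterministic settling
  Events ev; ev.on = false;
  double ov = maxOverlapFrac(W);
  int it = 0;
  while (ov >= tol_frac && it < max_iter) {
    mechStep(W, cfg, ev, 0);
    ov = maxOverlapFrac(W);
    ++it;
  }
  return List::create(_["world"] = worldToList(W),
                      _["max_overlap"] = ov, _["iterations"] = it);
}

// [[Rcpp::export]]
double cpp_max_overlap(List world) {
  World W = worldFromList(world);
  return maxOverlapFrac(W);
}

// grid-backed fixed-radius neighbor query; returns 1-based indices of points
// with center-to-center distance <= radius from (qx, qy)
// [[Rcpp::export]]
IntegerVector cpp_neighbors(NumericVector x, NumericVector y,
                            double qx, double qy, double radius) {
  size_t n = x.size();
  std::vector<double> vx(x.begin(), x.end()), vy(y.begin(), y.end());
  std::vector<int> out;
  if (n > 0 && radius <= 0) {
    for (size_t j = 0; j < n; ++j)
      if (vx[j] == qx && vy[j] == qy) out.push_back((int)j + 1);
  } else if (n > 0) {
    Grid g;
    g.build(vx, vy, std::max(radius / 3.0, 1.0));
    double r2 = radius * radius;
    g.forCandidates(qx, qy, radius, [&](int j) {
      double dx = vx[j] - qx, dy = vy[j] - qy;
      if (dx * dx + dy * dy <= r2) out.push_back(j + 1);
    });
  }
  std::sort(out.begin(), out.end());
  return IntegerVector(out.begin(), out.end());
}

// all touching pairs (center distance <= (r_i + r_j) * (1 + tol)), 1-based
// [[Rcpp::export]]
IntegerMatrix cpp_contacts(NumericVector x, NumericVector y, NumericVector r,
                           double tol) {
  size_t n = x.size();
  std::vector<double> vx(x.begin(), x.end()), vy(y.begin(), y.end()),
      vr(r.begin(), r.end());
  std::vector<std::pair<int, int>> pairs;
  if (n > 1) {
    double rmax = 0;
    for (size_t i = 0; i < n; ++i) rmax = std::max(rmax, vr[i]);
    Grid g;
    g.build(vx, vy, 2.0 * rmax * (1.0 + tol));
    for (size_t i = 0; i < n; ++i) {
      g.forCandidates(vx[i], vy[i], (vr[i] + rmax) * (1.0 + tol), [&](int j) {
        if ((size_t)j <= i) return;
        double dx = vx[j] - vx[i], dy = vy[j] - vy[i];
        double lim = (vr[i] + vr[j]) * (1.0 + tol);
        if (dx * dx + dy * dy <= lim * lim) pairs.push_back({(int)i + 1, j + 1});
      });
    }
  }
  std::sort(pairs.begin(), pairs.end());
  IntegerMatrix out((int)pairs.size(), 2);
  for (size_t k = 0; k < pairs.size(); ++k) {
    out(k, 0) = pairs[k].first;
    out(k, 1) = pairs[k].second;
  }
  return out;
}
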