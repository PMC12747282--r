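// Core integration kernel for the chemostat host-virus model.
//
// State: a lattice n(p, q) of cell counts over cell volume p (volume units,
// p0..2*p0) and intracellular virion count q (nodes of a possibly non-uniform
// grid), plus scalar nutrient (phi) and free-virus (psi) concentrations.
//
// Scheme: uniformization / exponential-Euler. For each lattice state the total
// outflow over dt is integrated exactly, n*(1 - exp(-R*dt)), and redistributed
// to destination states proportionally to the individual rates; phi and psi
// relax exactly toward their instantaneous fixed points, so at a stationary
// point the chemostat flux balances hold exactly. The scheme is positivity
// preserving for any dt. dt adapts to the largest transport rate (growth,
// replication, clearance, infection, dilution) among states carrying
// appreciable mass; the lysis hazard, which diverges at the lethal threshold,
// is integrated exactly and excluded from the dt control, which treats fast
// boundary states quasi-statically.
//
// For speed, long runs freeze the per-state redistribution coefficients over
// blocks of `recalc` steps (phi, psi and dt re-read at block boundaries); the
// exposed single-step entry point recomputes everything exactly per step.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct ChemPars {
  double A, B, C, E, F, G, T, phi0, psi0;
  int p0, Qmax;
};

static ChemPars parse_pars(const List& p) {
  ChemPars P;
  P.A = as<double>(p["A"]);   P.B = as<double>(p["B"]);
  P.C = as<double>(p["C"]);   P.E = as<double>(p["E"]);
  P.F = as<double>(p["F"]);   P.G = as<double>(p["G"]);
  P.T = as<double>(p["T"]);   P.phi0 = as<double>(p["phi0"]);
  P.psi0 = as<double>(p["psi0"]);
  P.p0 = as<int>(p["p0"]);    P.Qmax = as<int>(p["Q_max"]);
  return P;
}

// PCD/lysis clearance boundary in concentration units for a strategy.
static inline double strat_bound(const ChemPars& P, double a) {
  return (a > 0.0) ? std::min(P.T, 1.0 - a) : P.T;
}

static inline double hazard(double rho, const ChemPars& P) {
  if (rho <= 0.0) return 0.0;
  if (rho >= P.T) return R_PosInf;
  return std::pow(rho / (P.T - rho), P.G);
}

// [[Rcpp::export]]
IntegerVector cpp_build_qgrid(int qcap, int q_lin, double q_ratio) {
  std::vector<int> g;
  int top = std::min(qcap, q_lin);
  for (int q = 0; q <= top; ++q) g.push_back(q);
  double cur = (double) top;
  while (g.back() < qcap) {
    cur *= q_ratio;
    int nxt = std::max(g.back() + 1, (int) std::floor(cur));
    if (nxt >= qcap) { g.push_back(qcap); break; }
    g.push_back(nxt);
  }
  return wrap(g);
}

struct Control {
  double tol, t_max, t_min, eta, dt_max, check_every, floor_rel, qtop_rel;
  int recalc, q_lin;
  double q_ratio;
  bool record_burst;
};

static Control parse_control(const List& c) {
  Control K;
  K.tol = as<double>(c["tol"]);
  K.t_max = as<double>(c["t_max"]);
  K.t_min = as<double>(c["t_min"]);
  K.eta = as<double>(c["eta"]);
  K.dt_max = as<double>(c["dt_max"]);
  K.check_every = as<double>(c["check_every"]);
  K.floor_rel = as<double>(c["floor_rel"]);
  K.qtop_rel = as<double>(c["qtop_rel"]);
  K.recalc = as<int>(c["recalc"]);
  K.q_lin = as<int>(c["q_lin"]);
  K.q_ratio = as<double>(c["q_ratio"]);
  K.record_burst = as<bool>(c["record_burst"]);
  return K;
}

struct StepOut {
  double release = 0.0;    // virions released to psi by lysis
  double infected = 0.0;   // cells moved q=0 -> q=1 (virions consumed)
  double divisions = 0.0;  // division events
  double pcd = 0.0;        // cell mass destroyed by PCD
  double lysed = 0.0;      // cell mass lysed
  double washed = 0.0;     // cell mass diluted out
};

// One fully recomputed uniformization step (reference semantics; also the
// path behind the exposed single-step function and burst recording).
// n and nn are np x nk column-major (rows: p index, cols: q-node index);
// nn must be zeroed over the first min(nk_act+1, nk) columns.
static void step_lattice(const double* n, double* nn, int np, int nk,
                         int nk_act, const int* qg, const ChemPars& P,
                         double a, double r, double phi, double psi,
                         double dt, StepOut& out, double* burst) {
  const double bound = strat_bound(P, a);
  const bool pcd_first = (a > 0.0) && ((1.0 - a) <= P.T);
  const double gm = P.A * (1.0 - (P.E > 0.0 ? r / P.E : 0.0)) * phi;
  const int kmax = std::min(nk_act, nk);
  for (int k = 0; k < kmax; ++k) {
    const int q = qg[k];
    const double dq_up = (k + 1 < nk) ? (double)(qg[k + 1] - q) : 1.0;
    const double dq_dn = (k > 0) ? (double)(q - qg[k - 1]) : 1.0;
    for (int i = 0; i < np; ++i) {
      const double m = n[k * np + i];
      if (m <= 0.0) continue;
      const int p = P.p0 + i;
      const double rho = (double) q * P.p0 / ((double) P.Qmax * p);
      const bool top_p = (i == np - 1);
      double g = 0.0, f = 0.0, h = 0.0, lam = 0.0, inf = 0.0;
      if (!top_p || q == 0) g = gm * p;  // growth; division if top_p && q==0
      if (q > 0) {
        f = P.F * q / dq_up;             // virus replication q -> next node
        h = r * p / dq_dn;               // immunity clearance q -> prev node
        lam = hazard(rho, P);
      }
      if (q == 0) inf = P.C * psi * p;   // superinfection exclusion: q=0 only
      const double R = g + f + h + lam + inf + P.B;
      if (R <= 0.0) { nn[k * np + i] += m; continue; }
      const double outm = m * (-std::expm1(-R * dt));
      const double share = outm / R;
      nn[k * np + i] += m - outm;
      if (g > 0.0) {
        if (!top_p) nn[k * np + i + 1] += share * g;
        else { nn[0] += 2.0 * share * g; out.divisions += share * g; }
      }
      if (f > 0.0) {
        const int qn = (k + 1 < nk) ? qg[k + 1] : q + 1;
        const double rho_n = (double) qn * P.p0 / ((double) P.Qmax * p);
        if (k + 1 < nk && rho_n < bound) {
          nn[(k + 1) * np + i] += share * f;
        } else if (pcd_first) {
          out.pcd += share * f;          // PCD: mass and virions destroyed
        } else {
          out.release += share * f * qn; // burst at the lethal threshold
          out.lysed += share * f;
          if (burst) burst[std::min(k + 1, nk)] += share * f;
        }
      }
      if (h > 0.0) nn[(k - 1) * np + i] += share * h;
      if (lam > 0.0) {
        out.release += share * lam * q;  // lysis releases all q virions
        out.lysed += share * lam;
        if (burst) burst[k] += share * lam;
      }
      if (inf > 0.0) {
        // destination q=1 may itself lie beyond the PCD threshold (a near 1):
        // the virion is consumed but the cell dies immediately
        const double rho1 = (double) P.p0 / ((double) P.Qmax * p);
        if (rho1 < bound) nn[np + i] += share * inf;
        else out.pcd += share * inf;
        out.infected += share * inf;
      }
      out.washed += share * P.B;         // dilution: virions leave with cell
    }
  }
}

// Zero out lattice states at or beyond the clearance boundary; returns mass
// removed. Used when user-supplied states carry mass in the PCD region.
static double clear_inactive(double* n, int np, int nk, const int* qg,
                             const ChemPars& P, double a) {
  const double bound = strat_bound(P, a);
  double removed = 0.0;
  for (int k = 0; k < nk; ++k) {
    for (int i = 0; i < np; ++i) {
      const int p = P.p0 + i;
      const double rho = (double) qg[k] * P.p0 / ((double) P.Qmax * p);
      if (qg[k] > 0 && rho >= bound && n[k * np + i] > 0.0) {
        removed += n[k * np + i];
        n[k * np + i] = 0.0;
      }
    }
  }
  return removed;
}

// Exact exponential relaxation of phi and psi given start-of-step cell sums
// and the virion release of this step (converted to a rate).
static void scalar_update(const ChemPars& P, double V, double P0,
                          double release_amt, double dt,
                          double& phi, double& psi) {
  const double Rphi = P.B + P.C * V;
  const double phis = (Rphi > 0.0) ? P.phi0 * P.B / Rphi : P.phi0;
  phi = phis + (phi - phis) * std::exp(-Rphi * dt);
  const double Rpsi = P.B + P.C * P0;
  const double inflow = P.psi0 * P.B + (dt > 0.0 ? release_amt / dt : 0.0);
  const double psis = (Rpsi > 0.0) ? inflow / Rpsi : P.psi0;
  psi = psis + (psi - psis) * std::exp(-Rpsi * dt);
}

// ---------------------------------------------------------------------------
// A genotype lattice with frozen-coefficient block stepping.

struct Lattice {
  const ChemPars* P;
  double a, r;
  int np, nk;
  std::vector<int> qg;
  std::vector<double> cur, nxt;
  // frozen per-state coefficients (index k*np+i)
  std::vector<double> stay, cg, cf, ch, cinf, crel;
  int nact;          // columns currently integrated
  int extent;        // columns possibly nonzero (<= nk)
  double N, V, P0;   // start-of-step sums, maintained incrementally

  void init(const ChemPars* P_, double a_, double r_, int q_lin,
            double q_ratio) {
    P = P_; a = a_; r = r_;
    np = P->p0 + 1;
    const double bound = strat_bound(*P, a);
    const int qcap = std::max(1, (int) std::ceil(2.0 * bound * P->Qmax) - 1);
    IntegerVector g = cpp_build_qgrid(qcap, q_lin, q_ratio);
    qg.assign(g.begin(), g.end());
    nk = (int) qg.size();
    cur.assign((size_t) np * nk, 0.0);
    nxt.assign((size_t) np * nk, 0.0);
    const size_t sz = (size_t) np * nk;
    stay.assign(sz, 0.0); cg.assign(sz, 0.0); cf.assign(sz, 0.0);
    ch.assign(sz, 0.0); cinf.assign(sz, 0.0); crel.assign(sz, 0.0);
    nact = nk; extent = nk;
  }

  // map another lattice's mass onto this grid (largest node <= source q)
  void load(const double* n0, int np0, const int* qg0, int nk0) {
    int j = 0;
    for (int k0 = 0; k0 < nk0; ++k0) {
      while (j + 1 < nk && qg[j + 1] <= qg0[k0]) ++j;
      if (qg[j] > qg0[k0]) continue;
      for (int i = 0; i < std::min(np, np0); ++i)
        cur[(size_t) j * np + i] += n0[(size_t) k0 * np0 + i];
    }
    clear_inactive(cur.data(), np, nk, qg.data(), *P, a);
  }

  void sums() {
    N = 0.0; V = 0.0; P0 = 0.0;
    for (int k = 0; k < extent; ++k)
      for (int i = 0; i < np; ++i) {
        const double m = cur[(size_t) k * np + i];
        if (m <= 0.0) continue;
        N += m; V += m * (P->p0 + i);
        if (k == 0) P0 += m * (P->p0 + i);
      }
  }

  // Max transport rate among states with mass >= floor_rel*Nref (hazard
  // excluded), and highest column with mass >= qtop_rel*Nref.
  void rate_scan(double phi, double psi, double Nref, double floor_rel,
                 double qtop_rel, double& Rmax, int& ktop) const {
    const double gm = P->A * (1.0 - (P->E > 0.0 ? r / P->E : 0.0)) * phi;
    const double mfloor = floor_rel * Nref, qfloor = qtop_rel * Nref;
    const double bound = strat_bound(*P, a);
    Rmax = P->B; ktop = 0;
    for (int k = 0; k < extent; ++k) {
      const int q = qg[k];
      const double dq_up = (k + 1 < nk) ? (double)(qg[k + 1] - q) : 1.0;
      const double dq_dn = (k > 0) ? (double)(q - qg[k - 1]) : 1.0;
      for (int i = 0; i < np; ++i) {
        const double m = cur[(size_t) k * np + i];
        if (m <= 0.0) continue;
        if (m >= qfloor && k > ktop) ktop = k;
        if (m < mfloor) continue;
        const int p = P->p0 + i;
        double R = P->B + gm * p;
        if (q > 0) {
          // boundary-crossing replication is pure outflow (PCD or lysis);
          // like the hazard it is integrated exactly and excluded here
          const int qn = (k + 1 < nk) ? qg[k + 1] : q + 1;
          const double rho_n = (double) qn * P->p0 / ((double) P->Qmax * p);
          if (k + 1 < nk && rho_n < bound) R += P->F * q / dq_up;
          R += r * p / dq_dn;
        }
        // infection (q=0 -> 1) is also excluded: a single-jump transport
        // whose flux is quasi-statically correct when faster than the step
        if (R > Rmax) Rmax = R;
      }
    }
  }

  // set the active window after a rate scan; discards sub-threshold mass
  // beyond it so both buffers stay zero there
  void set_window(int ktop, int margin) {
    const int want = std::min(nk, ktop + 2 + margin);
    if (want < extent) {
      for (int k = want; k < extent; ++k)
        for (int i = 0; i < np; ++i) {
          cur[(size_t) k * np + i] = 0.0;
          nxt[(size_t) k * np + i] = 0.0;
        }
    }
    nact = want;
    extent = std::max(want, std::min(nk, want));
  }

  // freeze redistribution coefficients at (phi, psi, dt)
  void build_block(double phi, double psi, double dt) {
    const double bound = strat_bound(*P, a);
    const bool pcd_first = (a > 0.0) && ((1.0 - a) <= P->T);
    const double gm = P->A * (1.0 - (P->E > 0.0 ? r / P->E : 0.0)) * phi;
    const int kmax = std::min(nact, nk);
    for (int k = 0; k < kmax; ++k) {
      const int q = qg[k];
      const double dq_up = (k + 1 < nk) ? (double)(qg[k + 1] - q) : 1.0;
      const double dq_dn = (k > 0) ? (double)(q - qg[k - 1]) : 1.0;
      for (int i = 0; i < np; ++i) {
        const size_t idx = (size_t) k * np + i;
        const int p = P->p0 + i;
        const double rho = (double) q * P->p0 / ((double) P->Qmax * p);
        const bool top_p = (i == np - 1);
        double g = 0.0, f = 0.0, h = 0.0, lam = 0.0, inf = 0.0;
        if (!top_p || q == 0) g = gm * p;
        if (q > 0) {
          f = P->F * q / dq_up;
          h = r * p / dq_dn;
          lam = hazard(rho, *P);
        }
        if (q == 0) inf = P->C * psi * p;
        const double R = g + f + h + lam + inf + P->B;
        if (R <= 0.0) {
          stay[idx] = 1.0; cg[idx] = cf[idx] = ch[idx] = cinf[idx] =
            crel[idx] = 0.0;
          continue;
        }
        const double w = -std::expm1(-R * dt) / R;  // share per unit rate
        stay[idx] = 1.0 - w * R;
        cg[idx] = w * g;
        ch[idx] = w * h;
        // infection into a q=1 state beyond the PCD threshold kills at once
        cinf[idx] = (inf > 0.0 &&
                     (double) P->p0 / ((double) P->Qmax * p) >= bound)
                      ? 0.0 : w * inf;
        double rel = w * lam * q;
        double fdest = w * f;
        if (f > 0.0) {
          const int qn = (k + 1 < nk) ? qg[k + 1] : q + 1;
          const double rho_n = (double) qn * P->p0 / ((double) P->Qmax * p);
          if (!(k + 1 < nk && rho_n < bound)) {
            if (!pcd_first) rel += w * f * qn;  // boundary lysis
            fdest = 0.0;                        // destroyed or released
          }
        }
        cf[idx] = fdest;
        crel[idx] = rel;
      }
    }
  }

  // one frozen-coefficient step; accumulates released virions
  double step() {
    const int kmax = std::min(nact, nk);
    const int kclr = std::min(nact + 1, nk);
    std::fill(nxt.begin(), nxt.begin() + (size_t) np * kclr, 0.0);
    double release = 0.0;
    double N2 = 0.0, V2 = 0.0, Q2 = 0.0;
    for (int k = 0; k < kmax; ++k) {
      const bool top_k = (k + 1 >= nk);
      for (int i = 0; i < np; ++i) {
        const size_t idx = (size_t) k * np + i;
        const double m = cur[idx];
        if (m <= 0.0) continue;
        nxt[idx] += m * stay[idx];
        const double vg = m * cg[idx];
        if (vg > 0.0) {
          if (i + 1 < np) nxt[idx + 1] += vg;
          else nxt[0] += 2.0 * vg;      // division: two newborn cells
        }
        const double vf = m * cf[idx];
        if (vf > 0.0 && !top_k) nxt[idx + np] += vf;
        const double vh = m * ch[idx];
        if (vh > 0.0) nxt[idx - np] += vh;
        const double vi = m * cinf[idx];
        if (vi > 0.0) nxt[(size_t) np + i] += vi;
        release += m * crel[idx];
      }
    }
    // post-step sums over the possibly-written region
    for (int k = 0; k < kclr; ++k)
      for (int i = 0; i < np; ++i) {
        const double m = nxt[(size_t) k * np + i];
        if (m <= 0.0) continue;
        N2 += m; V2 += m * (P->p0 + i);
        if (k == 0) Q2 += m * (P->p0 + i);
      }
    cur.swap(nxt);
    extent = std::max(extent, kclr);
    N = N2; V = V2; P0 = Q2;
    return release;
  }

  NumericMatrix matrix() const {
    NumericMatrix m(np, nk);
    std::copy(cur.begin(), cur.end(), m.begin());
    return m;
  }
};

// ---------------------------------------------------------------------------
// Single exposed step (used by the R-level step() and the term-by-term
// oracle tests); fully recomputed, no coefficient freezing.
// [[Rcpp::export]]
List cpp_chemostat_step(NumericMatrix n, IntegerVector qgrid, double phi,
                        double psi, List pars, double a, double r, double dt) {
  const ChemPars P = parse_pars(pars);
  const int np = n.nrow(), nk = n.ncol();
  if (np != P.p0 + 1) stop("lattice must have p0+1 volume rows");
  std::vector<double> cur(n.begin(), n.end());
  const double pcd0 = clear_inactive(cur.data(), np, nk, qgrid.begin(), P, a);
  double N, V, P0;
  N = V = P0 = 0.0;
  for (int k = 0; k < nk; ++k)
    for (int i = 0; i < np; ++i) {
      const double m = cur[(size_t) k * np + i];
      N += m; V += m * (P.p0 + i);
      if (k == 0) P0 += m * (P.p0 + i);
    }
  std::vector<double> nn((size_t) np * nk, 0.0);
  std::vector<double> burst(nk + 1, 0.0);
  StepOut out;
  step_lattice(cur.data(), nn.data(), np, nk, nk, qgrid.begin(), P, a, r,
               phi, psi, dt, out, burst.data());
  scalar_update(P, V, P0, out.release, dt, phi, psi);
  NumericMatrix nmat(np, nk);
  std::copy(nn.begin(), nn.end(), nmat.begin());
  return List::create(
    _["n"] = nmat, _["phi"] = phi, _["psi"] = psi,
    _["release"] = out.release, _["infected"] = out.infected,
    _["divisions"] = out.divisions, _["pcd"] = out.pcd + pcd0,
    _["lysed"] = out.lysed, _["washed"] = out.washed,
    _["burst"] = NumericVector(burst.begin(), burst.end()));
}

// ---------------------------------------------------------------------------
// Integrate a single-genotype chemostat to (near) equilibrium.
// [[Rcpp::export]]
List cpp_run_chemostat(List pars, double a, double r, List control,
                       Nullable<List> init) {
  const ChemPars P = parse_pars(pars);
  const Control K = parse_control(control);
  Lattice L;
  L.init(&P, a, r, K.q_lin, K.q_ratio);
  double phi = P.phi0, psi = P.psi0;
  if (init.isNotNull()) {
    List is(init);
    NumericMatrix n0 = is["n"];
    IntegerVector qg0 = is["qgrid"];
    phi = as<double>(is["phi"]); psi = as<double>(is["psi"]);
    L.load(REAL(n0), n0.nrow(), qg0.begin(), qg0.size());
  } else {
    L.cur[0] = 1e-3 * P.B / (std::max(P.C, 1e-300) * P.p0);
  }
  L.sums();
  const double N_init = std::max(L.N, 1e-300);

  double Rmax; int ktop;
  L.rate_scan(phi, psi, L.N, K.floor_rel, K.qtop_rel, Rmax, ktop);
  L.set_window(ktop, K.recalc);
  double dt = std::min(K.eta / Rmax, K.dt_max);
  L.build_block(phi, psi, dt);

  double t = 0.0;
  double tN = L.N, tphi = phi, tpsi = psi, t_last = 0.0;
  double resid = R_PosInf;
  bool converged = false, extinct = false;
  long step = 0;
  const double gen = std::log(2.0) / std::max(P.A * P.phi0, 1e-300);

  while (t < K.t_max) {
    const double V = L.V, Q0 = L.P0;
    const double release = L.step();
    scalar_update(P, V, Q0, release, dt, phi, psi);
    t += dt; ++step;
    // extinction: relative floor (denormal drift) or below one whole cell
    if (L.N < 1e-9 * N_init || L.N < 1.0) { extinct = true; break; }
    if (step % K.recalc == 0) {
      L.rate_scan(phi, psi, L.N, K.floor_rel, K.qtop_rel, Rmax, ktop);
      L.set_window(ktop, K.recalc);
      dt = std::min(K.eta / Rmax, K.dt_max);
      L.build_block(phi, psi, dt);
      if (t - t_last >= K.check_every) {
        const double dN = std::fabs(L.N - tN) / std::max(L.N, 1e-300);
        const double dphi = std::fabs(phi - tphi) / std::max(phi, 1e-300);
        const double dpsi = std::fabs(psi - tpsi) / std::max(psi, 1e-300);
        resid = std::max(dN, std::max(dphi, dpsi)) * gen / (t - t_last);
        tN = L.N; tphi = phi; tpsi = psi; t_last = t;
        if (resid < K.tol && t >= K.t_min) { converged = true; break; }
      }
    }
  }

  NumericVector burst_mass(L.nk + 1);
  if (K.record_burst && !extinct && L.N > 0.0) {
    // one extra fully recomputed step recording the burst histogram
    std::vector<double> nn((size_t) L.np * L.nk, 0.0);
    StepOut out;
    step_lattice(L.cur.data(), nn.data(), L.np, L.nk, L.nk, L.qg.data(), P,
                 a, r, phi, psi, dt, out, burst_mass.begin());
  }
  return List::create(
    _["n"] = L.matrix(), _["qgrid"] = wrap(L.qg), _["phi"] = phi,
    _["psi"] = psi, _["t"] = t, _["steps"] = (double) step,
    _["converged"] = converged, _["residual"] = resid,
    _["extinct"] = extinct, _["N"] = extinct ? 0.0 : L.N, _["V"] = L.V,
    _["burst"] = burst_mass, _["dt"] = dt);
}

// ---------------------------------------------------------------------------
// Advance a two-genotype chemostat (shared phi and psi) for a fixed duration.
// Optionally records (t, N1, N2, phi, psi) every record_every time units.
// [[Rcpp::export]]
List cpp_advance_pair(NumericMatrix n1, IntegerVector qg1, double a1, double r1,
                      NumericMatrix n2, IntegerVector qg2, double a2, double r2,
                      double phi, double psi, List pars, double duration,
                      List control, double record_every) {
  const ChemPars P = parse_pars(pars);
  const Control K = parse_control(control);
  Lattice L1, L2;
  L1.init(&P, a1, r1, K.q_lin, K.q_ratio);
  L2.init(&P, a2, r2, K.q_lin, K.q_ratio);
  L1.load(REAL(n1), n1.nrow(), qg1.begin(), qg1.size());
  L2.load(REAL(n2), n2.nrow(), qg2.begin(), qg2.size());
  L1.sums(); L2.sums();

  std::vector<double> rt, rN1, rN2, rphi, rpsi;
  const bool rec = record_every > 0.0;
  double t = 0.0, t_rec = 0.0;
  if (rec) { rt.push_back(0.0); rN1.push_back(L1.N); rN2.push_back(L2.N);
             rphi.push_back(phi); rpsi.push_back(psi); }

  const double Ntot0 = std::max(L1.N + L2.N, 1e-300);
  double dt = K.dt_max;
  long step = 0;
  bool frozen = false;

  while (t < duration) {
    if (step % K.recalc == 0 || !frozen) {
      const double Nt = std::max(L1.N + L2.N, 1e-300);
      double R1 = P.B, R2 = P.B; int k1 = 0, k2 = 0;
      if (L1.N > 0.0) {
        L1.rate_scan(phi, psi, Nt, K.floor_rel, K.qtop_rel, R1, k1);
        L1.set_window(k1, K.recalc);
      }
      if (L2.N > 0.0) {
        L2.rate_scan(phi, psi, Nt, K.floor_rel, K.qtop_rel, R2, k2);
        L2.set_window(k2, K.recalc);
      }
      dt = std::min(K.eta / std::max(R1, R2), K.dt_max);
      if (t + dt > duration) dt = duration - t;
      if (L1.N > 0.0) L1.build_block(phi, psi, dt);
      if (L2.N > 0.0) L2.build_block(phi, psi, dt);
      frozen = true;
    }
    if (t + dt > duration) {
      // shorten the final step; rebuild coefficients for the new dt
      dt = duration - t;
      if (dt <= 1e-300) break;
      if (L1.N > 0.0) L1.build_block(phi, psi, dt);
      if (L2.N > 0.0) L2.build_block(phi, psi, dt);
    }
    const double V = L1.V + L2.V, Q0 = L1.P0 + L2.P0;
    double release = 0.0;
    if (L1.N > 0.0) release += L1.step();
    if (L2.N > 0.0) release += L2.step();
    scalar_update(P, V, Q0, release, dt, phi, psi);
    t += dt; ++step;
    if (L1.N + L2.N < 1e-12 * Ntot0) break;
    if (rec && t - t_rec >= record_every) {
      rt.push_back(t); rN1.push_back(L1.N); rN2.push_back(L2.N);
      rphi.push_back(phi); rpsi.push_back(psi);
      t_rec = t;
    }
  }
  List tr = R_NilValue;
  if (rec) {
    rt.push_back(t); rN1.push_back(L1.N); rN2.push_back(L2.N);
    rphi.push_back(phi); rpsi.push_back(psi);
    tr = List::create(_["t"] = wrap(rt), _["N1"] = wrap(rN1),
                      _["N2"] = wrap(rN2), _["phi"] = wrap(rphi),
                      _["psi"] = wrap(rpsi));
  }
  return List::create(
    _["n1"] = L1.matrix(), _["n2"] = L2.matrix(),
    _["qgrid1"] = wrap(L1.qg), _["qgrid2"] = wrap(L2.qg),
    _["phi"] = phi, _["psi"] = psi,
    _["N1"] = L1.N, _["N2"] = L2.N, _["t"] = t, _["trajectory"] = tr);
}
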