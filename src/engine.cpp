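// Lattice engine: cellular Potts dynamics, reaction-diffusion fields and the
// per-minute multiscale loop coupling them through the phenotype table.
//
// Cell type codes used throughout (match R side):
//   0 = medium / ECM, 1 = endothelial cell (EC), 2 = migrating tumour (M),
//   3 = proliferating tumour (P), 4 = quiescent tumour (Q), 5 = necrotic (N)

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static const int TYPE_MEDIUM = 0, TYPE_EC = 1, TYPE_M = 2, TYPE_P = 3,
                 TYPE_Q = 4, TYPE_N = 5;

// 6-neighbour (face) offsets, then the 12 edge neighbours for order-2 sums
static const int NB6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
static const int NB18[18][3] = {
  {1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1},
  {1,1,0},{1,-1,0},{-1,1,0},{-1,-1,0},
  {1,0,1},{1,0,-1},{-1,0,1},{-1,0,-1},
  {0,1,1},{0,1,-1},{0,-1,1},{0,-1,-1}};

struct Grid {
  int nx, ny, nz, n;
  Grid(IntegerVector dims) : nx(dims[0]), ny(dims[1]), nz(dims[2]) {
    n = nx * ny * nz;
  }
  inline int idx(int x, int y, int z) const { return x + nx * (y + ny * z); }
  inline void xyz(int i, int &x, int &y, int &z) const {
    x = i % nx; y = (i / nx) % ny; z = i / (nx * ny);
  }
  inline bool inside(int x, int y, int z) const {
    return x >= 0 && x < nx && y >= 0 && y < ny && z >= 0 && z < nz;
  }
};

// ---------------------------------------------------------------------------
// Mutable simulation view over the R state list (cloned on entry by callers)

struct Sim {
  Grid g;
  IntegerVector owner, type, volume, init_vol, competent, settle_min,
      hypoxia_min, necro_min, apop_min, ec_active, drug_q, grow_acc,
      apop_by_block;
  NumericVector tvol, cum_drug, n_field, V_field, c_field;
  int ncell;
  // per-cell voxel lists (rebuilt at entry)
  std::vector< std::vector<int> > vox;
  std::vector<int> stamp;  // BFS timestamps
  int stamp_ctr;
  std::vector<int> nb6tab;  // site*6+d -> neighbour index or -1
  std::vector<char> frag;   // per cell id: currently fragmented?

  void build_nb6() {
    if (!nb6tab.empty()) return;
    nb6tab.assign((size_t)g.n * 6, -1);
    for (int i = 0; i < g.n; ++i) {
      int x, y, z; g.xyz(i, x, y, z);
      for (int d = 0; d < 6; ++d) {
        int xx = x + NB6[d][0], yy = y + NB6[d][1], zz = z + NB6[d][2];
        if (g.inside(xx, yy, zz)) nb6tab[(size_t)i * 6 + d] = g.idx(xx, yy, zz);
      }
    }
  }

  void build_frag() {
    frag.assign(vox.size(), 0);
    for (size_t id = 1; id < vox.size(); ++id) {
      if (!vox[id].empty()) frag[id] = components((int)id) > 1 ? 1 : 0;
    }
  }

  Sim(List st) : g(st["dims"]),
    owner(as<IntegerVector>(st["owner"])),
    type(as<IntegerVector>(st["cell_type"])),
    volume(as<IntegerVector>(st["volume"])),
    init_vol(as<IntegerVector>(st["init_vol"])),
    competent(as<IntegerVector>(st["competent"])),
    settle_min(as<IntegerVector>(st["settle_min"])),
    hypoxia_min(as<IntegerVector>(st["hypoxia_min"])),
    necro_min(as<IntegerVector>(st["necro_min"])),
    apop_min(as<IntegerVector>(st["apop_min"])),
    ec_active(as<IntegerVector>(st["ec_active"])),
    drug_q(as<IntegerVector>(st["drug_q"])),
    grow_acc(as<IntegerVector>(st["grow_acc"])),
    apop_by_block(as<IntegerVector>(st["apop_by_block"])),
    tvol(as<NumericVector>(st["tvol"])),
    cum_drug(as<NumericVector>(st["cum_drug"])),
    n_field(as<NumericVector>(st["n_field"])),
    V_field(as<NumericVector>(st["V_field"])),
    c_field(as<NumericVector>(st["c_field"])),
    ncell(as<int>(st["ncell"])), stamp_ctr(0) {
    vox.resize(type.size() + 1);
    for (int i = 0; i < g.n; ++i) {
      int o = owner[i];
      if (o > 0) vox[o].push_back(i);
    }
    stamp.assign(g.n, 0);
    build_nb6();
    build_frag();
  }

  inline int type_of(int id) const { return id > 0 ? type[id - 1] : 0; }
  inline bool is_tumor(int id) const {
    int t = type_of(id); return t >= TYPE_M && t <= TYPE_N;
  }
  inline bool viable_tumor(int id) const {
    int t = type_of(id); return t >= TYPE_M && t <= TYPE_Q;
  }

  // connected components of a cell's voxel set, optionally excluding one
  // voxel (the one about to be lost) or including one extra (about to gain)
  int components(int id, int excl = -1, int incl = -1) {
    const std::vector<int> &vs = vox[id];
    int total = 0;
    ++stamp_ctr;
    int mark = stamp_ctr;
    // mark membership with stamp = mark (temporarily)
    for (size_t k = 0; k < vs.size(); ++k) {
      if (vs[k] != excl) { stamp[vs[k]] = mark; ++total; }
    }
    if (incl >= 0 && stamp[incl] != mark) { stamp[incl] = mark; ++total; }
    if (total == 0) return 0;
    int ncomp = 0;
    std::vector<int> queue;
    int visited_mark = mark;  // visited voxels get stamp = mark + ... use -mark trick
    // we flip stamp to -mark when visited
    int remaining = total;
    // iterate seeds over member voxels
    for (size_t k0 = 0; k0 <= vs.size(); ++k0) {
      int seed;
      if (k0 < vs.size()) { seed = vs[k0]; if (seed == excl) continue; }
      else { if (incl < 0) break; seed = incl; }
      if (stamp[seed] != visited_mark) continue;  // already visited (negative)
      ++ncomp;
      queue.clear(); queue.push_back(seed); stamp[seed] = -mark;
      while (!queue.empty()) {
        int cur = queue.back(); queue.pop_back();
        const int *nbt = &nb6tab[(size_t)cur * 6];
        for (int d = 0; d < 6; ++d) {
          int j = nbt[d];
          if (j >= 0 && stamp[j] == visited_mark) {
            stamp[j] = -mark; queue.push_back(j);
          }
        }
      }
      if (ncomp > 1) break;  // callers only distinguish 0 / 1 / >1
    }
    (void)remaining;
    return ncomp;
  }
};

// fragmentation indicator used by the continuity energy: a live cell whose
// voxel set splits into >1 face-connected component pays alpha once
static inline int fragmented(Sim &S, int id, int excl = -1, int incl = -1) {
  int nc = S.components(id, excl, incl);
  return nc > 1 ? 1 : 0;
}

// ---------------------------------------------------------------------------
// Energy terms

struct Params {
  NumericMatrix J;          // 6x6 by type
  NumericVector gamma;      // per type
  NumericVector chi;        // per type (<= 0)
  double alpha, Tm, kappa_conc;
  int adh_order;            // 1 (6-nb) or 2 (18-nb)
  Params(List p) : J(as<NumericMatrix>(p["J"])),
    gamma(as<NumericVector>(p["gamma"])),
    chi(as<NumericVector>(p["chi"])),
    alpha(as<double>(p["alpha"])), Tm(as<double>(p["Tm"])),
    kappa_conc(as<double>(p["kappa_conc"])),
    adh_order(as<int>(p["adh_order"])) {}
};

static double adhesion_delta(Sim &S, const Params &P, int site, int from,
                             int to) {
  int x, y, z; S.g.xyz(site, x, y, z);
  int tf = S.type_of(from), tt = S.type_of(to);
  double d = 0.0;
  int nnb = P.adh_order == 2 ? 18 : 6;
  const int (*NB)[3] = P.adh_order == 2 ? NB18 : NB6;
  for (int k = 0; k < nnb; ++k) {
    int xx = x + NB[k][0], yy = y + NB[k][1], zz = z + NB[k][2];
    if (!S.g.inside(xx, yy, zz)) continue;
    int o = S.owner[S.g.idx(xx, yy, zz)];
    int ty = S.type_of(o);
    if (o != to) d += P.J(tt, ty);
    if (o != from) d -= P.J(tf, ty);
  }
  return d;
}

static double growth_delta(Sim &S, const Params &P, int from, int to) {
  double d = 0.0;
  if (from > 0) {
    double v = S.volume[from - 1], T = S.tvol[from - 1],
           ga = P.gamma[S.type[from - 1]];
    d += ga * ((v - 1 - T) * (v - 1 - T) - (v - T) * (v - T));
  }
  if (to > 0) {
    double v = S.volume[to - 1], T = S.tvol[to - 1],
           ga = P.gamma[S.type[to - 1]];
    d += ga * ((v + 1 - T) * (v + 1 - T) - (v - T) * (v - T));
  }
  return d;
}

// Sufficient local criterion for a removal not to change the losing cell's
// component count: if every face-neighbour of `site` owned by the cell is
// connected to the others by face-paths inside the 3x3x3 box (excluding
// `site`), any global path through `site` reroutes locally, so the voxel is
// "simple" and connectivity is preserved. Returns false when inconclusive.
static bool local_safe_removal(Sim &S, int site, int from) {
  const int *nbt = &S.nb6tab[(size_t)site * 6];
  int anchors[6]; int k = 0;
  for (int d = 0; d < 6; ++d) {
    int j = nbt[d];
    if (j >= 0 && S.owner[j] == from) anchors[k++] = j;
  }
  if (k == 0) return false;  // isolated fragment: needs the global count
  if (k == 1) return true;   // pendant voxel cannot split the cell
  int x, y, z; S.g.xyz(site, x, y, z);
  int box[26]; int bx[26], by[26], bz[26]; int nb = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (!dx && !dy && !dz) continue;
        int xx = x + dx, yy = y + dy, zz = z + dz;
        if (!S.g.inside(xx, yy, zz)) continue;
        int j = S.g.idx(xx, yy, zz);
        if (S.owner[j] == from) {
          box[nb] = j; bx[nb] = xx; by[nb] = yy; bz[nb] = zz; ++nb;
        }
      }
  bool seen[26] = {false};
  int queue[26]; int qh = 0, qt = 0;
  for (int i = 0; i < nb; ++i) {
    if (box[i] == anchors[0]) { seen[i] = true; queue[qt++] = i; break; }
  }
  while (qh < qt) {
    int i = queue[qh++];
    for (int j = 0; j < nb; ++j) {
      if (seen[j]) continue;
      int man = std::abs(bx[i] - bx[j]) + std::abs(by[i] - by[j]) +
                std::abs(bz[i] - bz[j]);
      if (man == 1) { seen[j] = true; queue[qt++] = j; }
    }
  }
  for (int a = 1; a < k; ++a) {
    bool ok = false;
    for (int i = 0; i < nb; ++i) {
      if (box[i] == anchors[a] && seen[i]) { ok = true; break; }
    }
    if (!ok) return false;
  }
  return true;
}

static double continuity_delta(Sim &S, const Params &P, int site, int from,
                               int to) {
  double d = 0.0;
  if (from > 0) {
    int before = S.frag[from];
    int after;
    if (S.volume[from - 1] <= 1) after = 0;               // cell vanishes
    else if (local_safe_removal(S, site, from)) after = before;
    else after = S.components(from, site) > 1 ? 1 : 0;
    d += P.alpha * (after - before);
  }
  if (to > 0) {
    // adding a face-adjacent voxel cannot fragment a connected cell; it may
    // heal an already fragmented one
    int before = S.frag[to];
    int after = before ? (S.components(to, -1, site) > 1 ? 1 : 0) : 0;
    d += P.alpha * (after - before);
  }
  return d;
}

// chemotaxis for the extending (gaining) cell under the source-target copy
// convention; M cells read the nutrient field, activated ECs the VEGF field
static double chemotaxis_delta_sim(Sim &S, const Params &P, int site,
                                   int source_site, int to) {
  if (to <= 0) return 0.0;
  int ty = S.type[to - 1];
  if (ty == TYPE_M) {
    return P.chi[TYPE_M] * P.kappa_conc *
           (S.n_field[site] - S.n_field[source_site]);
  }
  if (ty == TYPE_EC && S.ec_active[to - 1]) {
    return P.chi[TYPE_EC] * P.kappa_conc *
           (S.V_field[site] - S.V_field[source_site]);
  }
  return 0.0;
}

static double delta_h(Sim &S, const Params &P, int site, int source_site,
                      int to, double *parts = 0) {
  int from = S.owner[site];
  double da = adhesion_delta(S, P, site, from, to);
  double dg = growth_delta(S, P, from, to);
  double dc = continuity_delta(S, P, site, from, to);
  double dx = chemotaxis_delta_sim(S, P, site, source_site, to);
  if (parts) { parts[0] = da; parts[1] = dg; parts[2] = dc; parts[3] = dx; }
  return da + dg + dc + dx;
}

static void apply_copy(Sim &S, int site, int to) {
  int from = S.owner[site];
  if (from == to) return;
  char new_from_frag = 0, new_to_frag = 0;
  if (from > 0) {
    if (S.volume[from - 1] <= 1) new_from_frag = 0;
    else if (local_safe_removal(S, site, from)) new_from_frag = S.frag[from];
    else new_from_frag = S.components(from, site) > 1 ? 1 : 0;
  }
  if (to > 0) {
    new_to_frag = S.frag[to] ? (S.components(to, -1, site) > 1 ? 1 : 0) : 0;
  }
  if (from > 0) {
    std::vector<int> &vf = S.vox[from];
    for (size_t k = 0; k < vf.size(); ++k) {
      if (vf[k] == site) { vf[k] = vf.back(); vf.pop_back(); break; }
    }
    S.volume[from - 1] -= 1;
  }
  if (to > 0) {
    S.vox[to].push_back(site);
    S.volume[to - 1] += 1;
  }
  S.owner[site] = to;
  if (from > 0) S.frag[from] = new_from_frag;
  if (to > 0) S.frag[to] = new_to_frag;
}

static inline bool mobile(Sim &S, int id, bool freeze_necrotic,
                          bool freeze_inactive_ec, bool freeze_quiescent) {
  if (id == 0) return true;
  int ty = S.type[id - 1];
  if (ty == TYPE_N && freeze_necrotic) return false;
  if (ty == TYPE_Q && freeze_quiescent) return false;
  if (ty == TYPE_EC && freeze_inactive_ec && !S.ec_active[id - 1]) return false;
  return true;
}

// one Monte Carlo step = N copy attempts at random sites/directions
static void mcs_sweep(Sim &S, const Params &P, bool freeze_necrotic,
                      bool freeze_inactive_ec, bool freeze_quiescent) {
  int N = S.g.n;
  const int *nbt = S.nb6tab.data();
  const int *own = INTEGER(S.owner);
  for (int a = 0; a < N; ++a) {
    // one uniform draw yields both the site and the direction
    double u = unif_rand() * N;
    int site = (int)u;
    if (site >= N) site = N - 1;
    int d = (int)((u - site) * 6);
    if (d >= 6) d = 5;
    int src = nbt[(size_t)site * 6 + d];
    if (src < 0) continue;
    int from = own[site], to = own[src];
    if (from == to) continue;
    if (!mobile(S, from, freeze_necrotic, freeze_inactive_ec,
                freeze_quiescent) ||
        !mobile(S, to, freeze_necrotic, freeze_inactive_ec,
                freeze_quiescent)) continue;
    // cheap terms first; while neither cell is fragmented the continuity
    // term cannot be negative, so a rejection on the partial bound is exact
    double dh_part = adhesion_delta(S, P, site, from, to) +
                     growth_delta(S, P, from, to) +
                     chemotaxis_delta_sim(S, P, site, src, to);
    bool lb_valid = (from <= 0 || !S.frag[from]) && (to <= 0 || !S.frag[to]);
    double uu = -1.0;
    if (lb_valid && dh_part > 0.0) {
      uu = unif_rand();
      if (uu >= std::exp(-dh_part / P.Tm)) continue;
    }
    double dh = dh_part + continuity_delta(S, P, site, from, to);
    bool acc;
    if (dh <= 0.0) acc = true;
    else {
      if (uu < 0.0) uu = unif_rand();
      acc = uu < std::exp(-dh / P.Tm);
    }
    if (acc) apply_copy(S, site, to);
  }
}

// ---------------------------------------------------------------------------
// Per-cell boundary statistics (contact fractions, field means)

struct CellStats {
  std::vector<int> bfaces, f_viable, f_ecm, f_ec;
  std::vector<double> sum_n, sum_V;
  void resize(int ncell) {
    bfaces.assign(ncell, 0); f_viable.assign(ncell, 0);
    f_ecm.assign(ncell, 0); f_ec.assign(ncell, 0);
    sum_n.assign(ncell, 0.0); sum_V.assign(ncell, 0.0);
  }
};

static void gather_stats(Sim &S, CellStats &cs) {
  cs.resize(S.ncell);
  for (int id = 1; id <= S.ncell; ++id) {
    if (S.type[id - 1] == 0) continue;
    const std::vector<int> &vs = S.vox[id];
    for (size_t k = 0; k < vs.size(); ++k) {
      int i = vs[k];
      cs.sum_n[id - 1] += S.n_field[i];
      cs.sum_V[id - 1] += S.V_field[i];
      const int *nbt = &S.nb6tab[(size_t)i * 6];
      for (int d = 0; d < 6; ++d) {
        int j = nbt[d];
        int o = j < 0 ? 0 : S.owner[j];  // domain wall counts as ECM
        if (o == id) continue;
        cs.bfaces[id - 1] += 1;
        if (o == 0) cs.f_ecm[id - 1] += 1;
        else if (S.viable_tumor(o)) cs.f_viable[id - 1] += 1;
        else if (S.type_of(o) == TYPE_EC) cs.f_ec[id - 1] += 1;
      }
    }
  }
}

// ---------------------------------------------------------------------------
// Reaction-diffusion kernels (explicit FTCS diffusion + exact decay,
// capped voxel-local uptake and sources)

static void diffuse_once(NumericVector &f, const Grid &g, double lam,
                         std::vector<double> &buf) {
  // lam = D * dt / dx^2; no-flux boundaries (missing neighbour contributes 0)
  for (int i = 0; i < g.n; ++i) buf[i] = f[i];
  for (int z = 0; z < g.nz; ++z)
    for (int y = 0; y < g.ny; ++y)
      for (int x = 0; x < g.nx; ++x) {
        int i = g.idx(x, y, z);
        double acc = 0.0, c = buf[i];
        if (x > 0)        acc += buf[i - 1] - c;
        if (x < g.nx - 1) acc += buf[i + 1] - c;
        if (y > 0)        acc += buf[i - g.nx] - c;
        if (y < g.ny - 1) acc += buf[i + g.nx] - c;
        if (z > 0)        acc += buf[i - g.nx * g.ny] - c;
        if (z < g.nz - 1) acc += buf[i + g.nx * g.ny] - c;
        f[i] = c + lam * acc;
      }
}

// [[Rcpp::export]]
NumericVector cpp_rd_step(NumericVector field, IntegerVector dims, double D,
                          double dt, double dx, NumericVector uptake_cap,
                          NumericVector source, double decay_k,
                          NumericVector clamp_max) {
  Grid g(dims);
  if (field.size() != g.n) stop("field size does not match dims");
  NumericVector f = clone(field);
  std::vector<double> buf(g.n);
  if (D > 0) {
    double lam = D * dt / (dx * dx);
    if (lam > 1.0 / 6.0 + 1e-12) {
      int need = (int)std::ceil(dt / (dx * dx / (6.0 * D)));
      stop("diffusion stability violated (D*dt/dx^2 = %f > 1/6); use >= %d sub-steps",
           lam, need);
    }
    diffuse_once(f, g, lam, buf);
  }
  double dk = decay_k > 0 ? std::exp(-decay_k * dt) : 1.0;
  bool has_cap = uptake_cap.size() == g.n;
  bool has_src = source.size() == g.n;
  bool has_clamp = clamp_max.size() == g.n;
  for (int i = 0; i < g.n; ++i) {
    double v = f[i] * dk;
    if (has_cap && uptake_cap[i] > 0) v -= std::min(v, uptake_cap[i] * dt);
    if (has_src) v += source[i] * dt;
    if (has_clamp && clamp_max[i] >= 0 && v > clamp_max[i]) v = clamp_max[i];
    f[i] = v < 0 ? 0 : v;
  }
  return f;
}

// [[Rcpp::export]]
List cpp_rd_relax(NumericVector field, IntegerVector dims, double D,
                  double dx, NumericVector uptake_cap, NumericVector source,
                  double decay_k, NumericVector clamp_max, double tol,
                  double max_time) {
  Grid g(dims);
  NumericVector f = clone(field);
  double dt = D > 0 ? 0.9 * dx * dx / (6.0 * D) : max_time;
  double t = 0.0;
  int steps = 0;
  bool converged = false;
  while (t < max_time) {
    double step_dt = std::min(dt, max_time - t);
    NumericVector nf = cpp_rd_step(f, dims, D, step_dt, dx, uptake_cap,
                                   source, decay_k, clamp_max);
    double dmax = 0.0, fmax = 0.0;
    for (int i = 0; i < g.n; ++i) {
      dmax = std::max(dmax, std::fabs(nf[i] - f[i]));
      fmax = std::max(fmax, std::fabs(nf[i]));
    }
    f = nf;
    t += step_dt;
    ++steps;
    if (dmax <= tol * std::max(fmax, 1e-300)) { converged = true; break; }
  }
  return List::create(_["field"] = f, _["time"] = t, _["steps"] = steps,
                      _["converged"] = converged);
}

// ---------------------------------------------------------------------------
// Field update within the production loop: reaction exact over the 60-s MCS,
// diffusion as a configured number of stable sub-steps (effective per-MCS
// diffusion operator; see the methods vignette)

struct FieldParams {
  double D_n, D_V, D_c, dx, k_V, k_c;
  double beta_P_vox, beta_Q_vox, s_n_vox, n_vessel, e_vox, s_V_mcs,
         kappa_P_vox;
  int nsub_n, nsub_V, nsub_c;
  double mcs_seconds;
  FieldParams(List p) : D_n(as<double>(p["D_n"])), D_V(as<double>(p["D_V"])),
    D_c(as<double>(p["D_c"])), dx(as<double>(p["dx"])),
    k_V(as<double>(p["k_V"])), k_c(as<double>(p["k_c"])),
    beta_P_vox(as<double>(p["beta_P_vox"])),
    beta_Q_vox(as<double>(p["beta_Q_vox"])),
    s_n_vox(as<double>(p["s_n_vox"])), n_vessel(as<double>(p["n_vessel"])),
    e_vox(as<double>(p["e_vox"])), s_V_mcs(as<double>(p["s_V_mcs"])),
    kappa_P_vox(as<double>(p["kappa_P_vox"])),
    nsub_n(as<int>(p["nsub_n"])), nsub_V(as<int>(p["nsub_V"])),
    nsub_c(as<int>(p["nsub_c"])), mcs_seconds(as<double>(p["mcs_seconds"])) {}
};

static void fields_update(Sim &S, const FieldParams &FP, double drug_src,
                          std::vector<double> &buf) {
  const Grid &g = S.g;
  double T = FP.mcs_seconds;
  double dkV = std::exp(-FP.k_V * T), dkc = std::exp(-FP.k_c * T);
  // reaction pass (exact over one MCS)
  for (int i = 0; i < g.n; ++i) {
    int o = S.owner[i];
    int ty = S.type_of(o);
    double n = S.n_field[i], V = S.V_field[i] * dkV, c = S.c_field[i] * dkc;
    if (ty == TYPE_P || ty == TYPE_M) {
      n -= std::min(n, FP.beta_P_vox * T);
      double take = std::min(c, FP.kappa_P_vox * T);
      c -= take;
      S.cum_drug[o - 1] += take;
    } else if (ty == TYPE_Q) {
      n -= std::min(n, FP.beta_Q_vox * T);
      if (S.drug_q[o - 1]) {  // drug-arrested cells keep taking up drug
        double take = std::min(c, FP.kappa_P_vox * T);
        c -= take;
        S.cum_drug[o - 1] += take;
      }
      if (S.hypoxia_min[o - 1] > 0) V += FP.s_V_mcs;  // hypoxic secretion
    } else if (ty == TYPE_N) {
      V += FP.s_V_mcs;
    } else if (ty == TYPE_EC) {
      n += FP.s_n_vox * T;
      if (n > FP.n_vessel) n = FP.n_vessel;  // vessel concentration cap
      V -= std::min(V, FP.e_vox * T);
      if (drug_src > 0) c += drug_src * T;
    }
    S.n_field[i] = n < 0 ? 0 : n;
    S.V_field[i] = V < 0 ? 0 : V;
    S.c_field[i] = c < 0 ? 0 : c;
  }
  // diffusion pass (stable explicit sub-steps); all-zero fields are skipped
  double tot_V = 0, tot_c = 0;
  for (int i = 0; i < g.n; ++i) { tot_V += S.V_field[i]; tot_c += S.c_field[i]; }
  if (FP.D_n > 0 && FP.nsub_n > 0) {
    double lam = 0.9 / 6.0;
    for (int s = 0; s < FP.nsub_n; ++s) diffuse_once(S.n_field, g, lam, buf);
  }
  if (FP.D_V > 0 && FP.nsub_V > 0 && tot_V > 0) {
    double lam = 0.9 / 6.0;
    for (int s = 0; s < FP.nsub_V; ++s) diffuse_once(S.V_field, g, lam, buf);
  }
  if (FP.D_c > 0 && FP.nsub_c > 0 && tot_c > 0) {
    double lam = 0.9 / 6.0;
    for (int s = 0; s < FP.nsub_c; ++s) diffuse_once(S.c_field, g, lam, buf);
  }
  // re-apply the vessel cap after diffusion so EC voxels track the vessel
  for (int i = 0; i < g.n; ++i) {
    if (S.type_of(S.owner[i]) == TYPE_EC && S.n_field[i] > FP.n_vessel)
      S.n_field[i] = FP.n_vessel;
  }
}

// ---------------------------------------------------------------------------
// Cell state machine + growth/division

struct BioParams {
  double T_RTK, T_RTK_Q, T_ITG, T_cad, T_wnt, T_v, theta_VE;
  int tau_N, tau_clear, tau_adh, tau_apop;
  int G_grow, lag_max;
  double theta1, theta2, repair_factor;
  int apc_on, nf1_on;
  BioParams(List p) : T_RTK(as<double>(p["T_RTK"])),
    T_RTK_Q(as<double>(p["T_RTK_Q"])), T_ITG(as<double>(p["T_ITG"])),
    T_cad(as<double>(p["T_cad"])), T_wnt(as<double>(p["T_wnt"])),
    T_v(as<double>(p["T_v"])), theta_VE(as<double>(p["theta_VE"])),
    tau_N(as<int>(p["tau_N"])), tau_clear(as<int>(p["tau_clear"])),
    tau_adh(as<int>(p["tau_adh"])), tau_apop(as<int>(p["tau_apop"])),
    G_grow(as<int>(p["G_grow"])), lag_max(as<int>(p["lag_max"])),
    theta1(as<double>(p["theta1"])), theta2(as<double>(p["theta2"])),
    repair_factor(as<double>(p["repair_factor"])),
    apc_on(as<int>(p["apc_on"])), nf1_on(as<int>(p["nf1_on"])) {}
};

struct Counters {
  long births, deaths_apop, drug_necro, killed_therapy;
};

// phenotype table index: bit0 = integrin, 1 = RTK, 2 = cadherin, 3 = Wnt,
// 4 = APC, 5 = NF1; value bits: 8 = growth, 4 = proliferation,
// 2 = apoptosis, 1 = migration
static void biology_update(Sim &S, const BioParams &B,
                           const IntegerVector &pheno_table, int block_mask,
                           CellStats &cs, Counters &ct) {
  gather_stats(S, cs);
  for (int id = 1; id <= S.ncell; ++id) {
    int k = id - 1;
    int ty = S.type[k];
    if (ty == 0) continue;
    if (S.volume[k] <= 0) {  // shrunk out
      if (S.apop_min[k] >= 0) {
        ct.deaths_apop += 1;
        if (S.apop_by_block[k]) ct.killed_therapy += 1;
      }
      S.type[k] = 0;
      continue;
    }
    double bf = cs.bfaces[k] > 0 ? (double)cs.bfaces[k] : 1.0;
    double frac_viable = cs.f_viable[k] / bf;
    double frac_ecm = cs.f_ecm[k] / bf;
    double frac_ec = cs.f_ec[k] / bf;
    double mean_n = cs.sum_n[k] / S.volume[k];
    double mean_V = cs.sum_V[k] / S.volume[k];

    if (ty == TYPE_EC) {
      if (!S.ec_active[k] && mean_V >= B.T_v) S.ec_active[k] = 1;
      if (S.ec_active[k] && (frac_ec < B.theta_VE || B.theta_VE >= 1.0)) {
        // VE-cadherin junctions below contact-inhibition level: stalk growth
        S.grow_acc[k] += 1;
        if (S.grow_acc[k] >= B.G_grow) {
          S.grow_acc[k] = 0;
          if (S.tvol[k] - S.volume[k] <= B.lag_max) S.tvol[k] += 1;
        }
      }
      continue;
    }
    if (ty == TYPE_N) {
      S.necro_min[k] += 1;
      if (S.necro_min[k] >= B.tau_clear) {
        for (size_t q = 0; q < S.vox[id].size(); ++q) S.owner[S.vox[id][q]] = 0;
        S.vox[id].clear();
        S.volume[k] = 0;
        S.type[k] = 0;
        S.frag[id] = 0;
      }
      continue;
    }

    // --- viable tumour cell (M/P/Q) ---
    // junction maturation (proliferation competence)
    if (!S.competent[k]) {
      if (frac_viable >= B.T_cad) S.settle_min[k] += 1; else S.settle_min[k] = 0;
      if (S.settle_min[k] >= B.tau_adh) S.competent[k] = 1;
    }
    // chemotherapy damage: cumulative uptake decays by repair; crossing
    // theta1 arrests the cell (reversibly), crossing theta2 kills it
    S.cum_drug[k] *= B.repair_factor;
    if (S.cum_drug[k] >= B.theta2) {
      S.type[k] = TYPE_N;
      S.necro_min[k] = 0;
      ct.drug_necro += 1;
      ct.killed_therapy += 1;
      continue;
    }
    if (S.cum_drug[k] >= B.theta1) S.drug_q[k] = 1;
    else if (S.drug_q[k]) S.drug_q[k] = 0;  // damage repaired: cycling resumes

    bool block_itg = (block_mask & 1) != 0, block_rtk = (block_mask & 2) != 0,
         block_cad = (block_mask & 4) != 0, block_wnt = (block_mask & 8) != 0;
    double rtk_thr = (ty == TYPE_Q && !S.drug_q[k]) ? B.T_RTK_Q : B.T_RTK;
    bool nutrient_ok = mean_n >= rtk_thr;

    if (!nutrient_ok && !block_rtk) {
      // nutrient-driven RTK silence: quiescence, not network apoptosis
      S.type[k] = TYPE_Q;
      S.hypoxia_min[k] += 1;
      if (S.apop_min[k] >= 0 && S.apop_min[k] < B.tau_apop) S.apop_min[k] = -1;
      if (S.hypoxia_min[k] >= B.tau_N) {
        S.type[k] = TYPE_N;
        S.necro_min[k] = 0;
      }
      continue;
    }
    S.hypoxia_min[k] = 0;

    // In tissue the matrix pervades the intercellular space, so an adherent
    // tumour cell keeps integrin engagement even when fully surrounded by
    // other cells; geometric loss of free ECM surface therefore does not
    // route interior cells into the apoptosis attractor. Integrin turns off
    // only under targeted blockade (or scenario knock-outs).
    int itg = block_itg ? 0 : 1;
    (void)frac_ecm;
    int rtk = block_rtk ? 0 : 1;  // nutrient_ok here
    int cad = (!block_cad && frac_viable >= B.T_cad) ? 1 : 0;
    int wnt = (!block_wnt && frac_viable < B.T_wnt) ? 1 : 0;
    int idx = itg + 2 * rtk + 4 * cad + 8 * wnt + 16 * B.apc_on + 32 * B.nf1_on;
    int code = pheno_table[idx];
    bool ph_growth = (code & 8) != 0, ph_prolif = (code & 4) != 0,
         ph_apop = (code & 2) != 0, ph_migr = (code & 1) != 0;
    bool blocked_any = block_mask != 0;

    if (ph_apop || (S.apop_min[k] >= B.tau_apop)) {
      if (S.apop_min[k] < 0) {
        S.apop_min[k] = 0;
        S.apop_by_block[k] = blocked_any ? 1 : 0;
      } else {
        S.apop_min[k] += 1;
      }
      if (S.apop_min[k] >= B.tau_apop) S.tvol[k] = 0;  // committed: shrink out
      continue;
    }
    if (S.apop_min[k] >= 0) S.apop_min[k] = -1;  // signalling restored in time

    if (S.drug_q[k]) {  // drug-arrested: stays quiescent
      S.type[k] = TYPE_Q;
      continue;
    }
    S.type[k] = ph_migr ? TYPE_M : TYPE_P;
    if (ph_growth && ph_prolif && S.competent[k]) {
      S.grow_acc[k] += 1;
      if (S.grow_acc[k] >= B.G_grow) {
        S.grow_acc[k] = 0;
        if (S.tvol[k] - S.volume[k] <= B.lag_max) S.tvol[k] += 1;
      }
    }
  }
}

// split a cell at the median of voxel projections onto a random plane
// normal; ties stay with the parent, daughter gets a fresh id
static void divide_cells(Sim &S, Counters &ct) {
  int ncell0 = S.ncell;
  for (int id = 1; id <= ncell0; ++id) {
    int k = id - 1;
    int ty = S.type[k];
    if (ty == 0 || ty == TYPE_Q || ty == TYPE_N) continue;
    if (ty == TYPE_EC && !S.ec_active[k]) continue;
    if (S.volume[k] < 2 * S.init_vol[k]) continue;
    if (S.volume[k] < 2) continue;  // 1-voxel cell: division deferred
    if (S.ncell >= (int)S.type.size()) {
      stop("cell capacity exceeded (%d); rebuild the scenario with a larger max_cells",
           (int)S.type.size());
    }
    std::vector<int> &vs = S.vox[id];
    // random unit normal (Marsaglia polar using R's RNG)
    double ux, uy, uz, ss;
    do {
      ux = 2 * unif_rand() - 1; uy = 2 * unif_rand() - 1;
      uz = 2 * unif_rand() - 1;
      ss = ux * ux + uy * uy + uz * uz;
    } while (ss < 1e-8 || ss > 1.0);
    double inv = 1.0 / std::sqrt(ss);
    ux *= inv; uy *= inv; uz *= inv;
    std::vector<double> proj(vs.size());
    for (size_t q = 0; q < vs.size(); ++q) {
      int x, y, z; S.g.xyz(vs[q], x, y, z);
      proj[q] = ux * x + uy * y + uz * z;
    }
    std::vector<double> sorted = proj;
    std::nth_element(sorted.begin(), sorted.begin() + sorted.size() / 2,
                     sorted.end());
    double med = sorted[sorted.size() / 2];
    std::vector<int> keep, give;
    for (size_t q = 0; q < vs.size(); ++q) {
      if (proj[q] > med) give.push_back(vs[q]); else keep.push_back(vs[q]);
    }
    if (give.empty() || keep.empty()) continue;  // degenerate: defer
    int did = ++S.ncell;
    int dk = did - 1;
    for (size_t q = 0; q < give.size(); ++q) S.owner[give[q]] = did;
    S.vox[did] = give;
    S.vox[id] = keep;
    S.volume[k] = (int)keep.size();
    S.volume[dk] = (int)give.size();
    S.type[dk] = ty;
    S.init_vol[dk] = S.init_vol[k];
    S.tvol[k] = S.init_vol[k];
    S.tvol[dk] = S.init_vol[k];
    S.competent[dk] = 1;  // junctions inherited from the parent
    S.settle_min[dk] = S.settle_min[k];
    S.hypoxia_min[dk] = 0;
    S.necro_min[dk] = 0;
    S.apop_min[dk] = -1;
    S.ec_active[dk] = S.ec_active[k];
    S.drug_q[dk] = S.drug_q[k];
    S.grow_acc[dk] = 0;
    S.apop_by_block[dk] = 0;
    S.cum_drug[dk] = S.cum_drug[k];  // mitotic damage carries over
    S.frag[id] = S.components(id) > 1 ? 1 : 0;
    S.frag[did] = S.components(did) > 1 ? 1 : 0;
    // the births counter feeds the FKC at-risk population, which is a
    // tumour-cell quantity; endothelial stalk divisions show up in n_EC
    if (ty != TYPE_EC) ct.births += 1;
  }
}

static bool tumor_at_boundary(Sim &S) {
  const Grid &g = S.g;
  for (int id = 1; id <= S.ncell; ++id) {
    if (!S.is_tumor(id) || S.type[id - 1] == 0) continue;
    const std::vector<int> &vs = S.vox[id];
    for (size_t q = 0; q < vs.size(); ++q) {
      int x, y, z; g.xyz(vs[q], x, y, z);
      if (x == 0 || y == 0 || z == 0 || x == g.nx - 1 || y == g.ny - 1 ||
          z == g.nz - 1) return true;
    }
  }
  return false;
}

// ---------------------------------------------------------------------------
// Exported simulation entry points

static List state_out(Sim &S, List st, Counters &ct, int clock_mcs,
                      bool stopped) {
  List out = clone(st);
  out["owner"] = S.owner; out["cell_type"] = S.type; out["volume"] = S.volume;
  out["init_vol"] = S.init_vol; out["competent"] = S.competent;
  out["settle_min"] = S.settle_min; out["hypoxia_min"] = S.hypoxia_min;
  out["necro_min"] = S.necro_min; out["apop_min"] = S.apop_min;
  out["ec_active"] = S.ec_active; out["drug_q"] = S.drug_q;
  out["grow_acc"] = S.grow_acc; out["apop_by_block"] = S.apop_by_block;
  out["tvol"] = S.tvol; out["cum_drug"] = S.cum_drug;
  out["n_field"] = S.n_field; out["V_field"] = S.V_field;
  out["c_field"] = S.c_field; out["ncell"] = S.ncell;
  out["clock_mcs"] = clock_mcs;
  out["births"] = (double)ct.births;
  out["deaths_apop"] = (double)ct.deaths_apop;
  out["drug_necro"] = (double)ct.drug_necro;
  out["killed_therapy"] = (double)ct.killed_therapy;
  out["stopped"] = stopped;
  return out;
}

static void trace_row(Sim &S, Counters &ct, int clock_mcs,
                      std::vector<double> &row) {
  int nP = 0, nQ = 0, nM = 0, nN = 0, nEC = 0, nECa = 0;
  long tum_vox = 0;
  for (int id = 1; id <= S.ncell; ++id) {
    int k = id - 1, ty = S.type[k];
    if (ty == 0) continue;
    if (ty == TYPE_P) ++nP;
    else if (ty == TYPE_Q) ++nQ;
    else if (ty == TYPE_M) ++nM;
    else if (ty == TYPE_N) ++nN;
    else if (ty == TYPE_EC) { ++nEC; if (S.ec_active[k]) ++nECa; }
    if (ty >= TYPE_M && ty <= TYPE_N) tum_vox += S.volume[k];
  }
  double tn = 0, tV = 0, tc = 0;
  for (int i = 0; i < S.g.n; ++i) {
    tn += S.n_field[i]; tV += S.V_field[i]; tc += S.c_field[i];
  }
  row[0] = clock_mcs; row[1] = nP; row[2] = nQ; row[3] = nM; row[4] = nN;
  row[5] = nEC; row[6] = nECa; row[7] = (double)tum_vox;
  row[8] = (double)ct.births; row[9] = (double)ct.deaths_apop;
  row[10] = (double)ct.drug_necro; row[11] = (double)ct.killed_therapy;
  row[12] = tn; row[13] = tV; row[14] = tc;
}

// [[Rcpp::export]]
List cpp_run(List state, List params, int n_mcs, int trace_every,
             bool do_cpm = true, bool do_biology = true,
             bool do_fields = true) {
  List st = clone(state);
  Sim S(st);
  Params P(params);
  FieldParams FP(params);
  BioParams B(params);
  bool freeze_necrotic = as<bool>(params["freeze_necrotic"]);
  bool freeze_inactive_ec = as<bool>(params["freeze_inactive_ec"]);
  bool freeze_quiescent = as<bool>(params["freeze_quiescent"]);
  IntegerVector pheno_table = as<IntegerVector>(params["pheno_table"]);
  NumericVector drug_src_mcs = as<NumericVector>(params["drug_src_mcs"]);
  IntegerVector block_mask_mcs = as<IntegerVector>(params["block_mask_mcs"]);
  int mcs_per_day = as<int>(params["mcs_per_day"]);
  int clock = as<int>(st["clock_mcs"]);
  Counters ct;
  ct.births = (long)as<double>(st["births"]);
  ct.deaths_apop = (long)as<double>(st["deaths_apop"]);
  ct.drug_necro = (long)as<double>(st["drug_necro"]);
  ct.killed_therapy = (long)as<double>(st["killed_therapy"]);
  CellStats cs;
  std::vector<double> buf(S.g.n);
  int nrow = (trace_every > 0 ? n_mcs / trace_every : 0) + 2;
  std::vector< std::vector<double> > trace;
  trace.reserve(nrow);
  std::vector<double> row(15);
  bool stopped = false;
  (void)mcs_per_day;
  for (int m = 0; m < n_mcs; ++m) {
    int bm = clock < block_mask_mcs.size() ? block_mask_mcs[clock] : 0;
    double dsrc = clock < drug_src_mcs.size() ? drug_src_mcs[clock] : 0.0;
    if (do_biology) biology_update(S, B, pheno_table, bm, cs, ct);
    if (do_cpm) mcs_sweep(S, P, freeze_necrotic, freeze_inactive_ec,
                          freeze_quiescent);
    if (do_biology) divide_cells(S, ct);
    if (do_fields) fields_update(S, FP, dsrc, buf);
    ++clock;
    if (trace_every > 0 && clock % trace_every == 0) {
      trace_row(S, ct, clock, row);
      trace.push_back(row);
      if (tumor_at_boundary(S)) { stopped = true; break; }
    }
    if (m % 256 == 0) Rcpp::checkUserInterrupt();
  }
  if (trace_every > 0 && clock % trace_every != 0) {
    trace_row(S, ct, clock, row);
    trace.push_back(row);
  }
  List out = state_out(S, st, ct, clock, stopped);
  int tr = (int)trace.size();
  NumericMatrix tr2(tr, 15);
  for (int i = 0; i < tr; ++i)
    for (int j = 0; j < 15; ++j) tr2(i, j) = trace[i][j];
  colnames(tr2) = CharacterVector::create(
      "mcs", "n_P", "n_Q", "n_M", "n_N", "n_EC", "n_EC_active", "tumor_vox",
      "births", "deaths_apop", "drug_necro", "killed_therapy", "total_n",
      "total_V", "total_c");
  return List::create(_["state"] = out, _["trace"] = tr2);
}

// [[Rcpp::export]]
NumericVector cpp_delta_h(List state, List params, int site, int source_site,
                          int cand_owner) {
  List st = clone(state);
  Sim S(st);
  Params P(params);
  if (site < 1 || site > S.g.n) stop("site out of range");
  double parts[4] = {0, 0, 0, 0};
  double dh = 0.0;
  if (S.owner[site - 1] != cand_owner) {  // a null copy changes nothing
    dh = delta_h(S, P, site - 1, source_site - 1, cand_owner, parts);
  }
  NumericVector out = NumericVector::create(
      _["total"] = dh, _["adhesion"] = parts[0], _["growth"] = parts[1],
      _["continuity"] = parts[2], _["chemotaxis"] = parts[3]);
  return out;
}

// [[Rcpp::export]]
double cpp_total_adhesion(IntegerVector owner, IntegerVector dims,
                          IntegerVector cell_type, NumericMatrix J,
                          int adh_order) {
  Grid g(dims);
  double e = 0.0;
  int nnb = adh_order == 2 ? 18 : 6;
  const int (*NB)[3] = adh_order == 2 ? NB18 : NB6;
  for (int z = 0; z < g.nz; ++z)
    for (int y = 0; y < g.ny; ++y)
      for (int x = 0; x < g.nx; ++x) {
        int i = g.idx(x, y, z);
        int oi = owner[i];
        int ti = oi > 0 ? cell_type[oi - 1] : 0;
        for (int k = 0; k < nnb; ++k) {
          int xx = x + NB[k][0], yy = y + NB[k][1], zz = z + NB[k][2];
          if (!g.inside(xx, yy, zz)) continue;
          int j = g.idx(xx, yy, zz);
          if (j <= i) continue;  // each unordered pair once
          int oj = owner[j];
          if (oi == oj) continue;
          int tj = oj > 0 ? cell_type[oj - 1] : 0;
          e += J(ti, tj);
        }
      }
  return e;
}

// [[Rcpp::export]]
IntegerVector cpp_cell_components(IntegerVector owner, IntegerVector dims,
                                  int ncell) {
  Grid g(dims);
  std::vector< std::vector<int> > vox(ncell + 1);
  for (int i = 0; i < g.n; ++i) {
    int o = owner[i];
    if (o > 0 && o <= ncell) vox[o].push_back(i);
  }
  IntegerVector ncomp(ncell);
  std::vector<int> stamp(g.n, 0);
  int mark = 0;
  std::vector<int> queue;
  for (int id = 1; id <= ncell; ++id) {
    ++mark;
    const std::vector<int> &vs = vox[id];
    for (size_t k = 0; k < vs.size(); ++k) stamp[vs[k]] = mark;
    int nc = 0;
    for (size_t k = 0; k < vs.size(); ++k) {
      if (stamp[vs[k]] != mark) continue;
      ++nc;
      queue.clear(); queue.push_back(vs[k]); stamp[vs[k]] = -mark;
      while (!queue.empty()) {
        int cur = queue.back(); queue.pop_back();
        int x, y, z; g.xyz(cur, x, y, z);
        for (int d = 0; d < 6; ++d) {
          int xx = x + NB6[d][0], yy = y + NB6[d][1], zz = z + NB6[d][2];
          if (!g.inside(xx, yy, zz)) continue;
          int j = g.idx(xx, yy, zz);
          if (stamp[j] == mark) { stamp[j] = -mark; queue.push_back(j); }
        }
      }
    }
    ncomp[id - 1] = nc;
  }
  return ncomp;
}

// [[Rcpp::export]]
List cpp_cell_stats(List state) {
  List st = clone(state);
  Sim S(st);
  CellStats cs;
  gather_stats(S, cs);
  int n = S.ncell;
  IntegerVector bf(n), fv(n), fe(n), fec(n), vol(n);
  NumericVector sn(n), sV(n);
  for (int k = 0; k < n; ++k) {
    bf[k] = cs.bfaces[k]; fv[k] = cs.f_viable[k]; fe[k] = cs.f_ecm[k];
    fec[k] = cs.f_ec[k]; sn[k] = cs.sum_n[k]; sV[k] = cs.sum_V[k];
    vol[k] = S.volume[k];
  }
  return List::create(_["volume"] = vol, _["boundary_faces"] = bf,
                      _["faces_viable_tumor"] = fv, _["faces_ecm"] = fe,
                      _["faces_ec"] = fec, _["sum_nutrient"] = sn,
                      _["sum_vegf"] = sV);
}

// [[Rcpp::export]]
List cpp_divide(List state) {
  List st = clone(state);
  Sim S(st);
  Counters ct;
  ct.births = (long)as<double>(st["births"]);
  ct.deaths_apop = ct.drug_necro = ct.killed_therapy = 0;
  divide_cells(S, ct);
  st["owner"] = S.owner; st["cell_type"] = S.type; st["volume"] = S.volume;
  st["init_vol"] = S.init_vol; st["tvol"] = S.tvol; st["ncell"] = S.ncell;
  st["competent"] = S.competent; st["ec_active"] = S.ec_active;
  st["drug_q"] = S.drug_q; st["cum_drug"] = S.cum_drug;
  st["births"] = (double)ct.births;
  return st;
}

// [[Rcpp::export]]
LogicalVector cpp_metropolis(NumericVector dh, double Tm) {
  int n = dh.size();
  LogicalVector acc(n);
  for (int i = 0; i < n; ++i) {
    acc[i] = dh[i] <= 0.0 || unif_rand() < std::exp(-dh[i] / Tm);
  }
  return acc;
}
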