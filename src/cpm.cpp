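// Extended cellular Potts engine on a hexagonal (honeycomb) lattice.
//
// Sites are indexed row-major on an "odd-r" offset grid: site = row*ncol + col,
// with Cartesian embedding x = col + 0.5*(row odd), y = (sqrt(3)/2)*row and
// lattice constant 1.  Each cell is a contiguous set of sites carrying a
// per-site polarization field eps in [eps0 - deps/2, eps0 + deps/2] and an
// integer regulatory accumulator F reset at the end of every Monte-Carlo step.
//
// Elementary events are copy attempts across directed boundary pairs
// (source, target) with distinct owners; acceptance is Metropolis-Hastings at
// temperature kBT with the proposal-ratio factor accounting for the
// state-dependent size of the boundary-pair set (detailed balance w.r.t. H
// when the feedback is switched off).

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <random>
#include <algorithm>
#include <cstdint>
#include <unordered_set>
#include <unordered_map>

using namespace Rcpp;

static const double HEXH = 0.8660254037844386; // sqrt(3)/2

// cyclic direction order around a site: E, NE, NW, W, SW, SE
// opposite(d) = (d+3) % 6; Cartesian step per direction (parity independent)
static const double DIR_DX[6] = { 1.0, 0.5, -0.5, -1.0, -0.5, 0.5 };
static const double DIR_DY[6] = { 0.0, -HEXH, -HEXH, 0.0, HEXH, HEXH };

struct HexLattice {
  int ncol = 0, nrow = 0;
  bool px = true, py = true;          // periodic in x (cols) / y (rows)
  std::vector<int> nbr;               // 6*N neighbor indices, -1 = absent

  int N() const { return ncol * nrow; }
  double xcoord(int s) const {
    int r = s / ncol, c = s % ncol;
    return c + 0.5 * (r & 1);
  }
  double ycoord(int s) const { return HEXH * (s / ncol); }

  void build(int ncol_, int nrow_, bool px_, bool py_) {
    if (ncol_ < 1 || nrow_ < 1) stop("lattice dimensions must be positive");
    if (py_ && nrow_ > 1 && (nrow_ % 2) != 0)
      stop("periodic y requires an even number of rows (offset-row parity)");
    ncol = ncol_; nrow = nrow_; px = px_; py = py_;
    nbr.assign(6 * (size_t)N(), -1);
    for (int r = 0; r < nrow; ++r) {
      const bool odd = (r & 1);
      // offsets (dc, dr) per direction, row-parity dependent
      const int dc_even[6] = { 1, 0, -1, -1, -1, 0 };
      const int dc_odd[6]  = { 1, 1,  0, -1,  0, 1 };
      const int dr[6]      = { 0, -1, -1, 0, 1, 1 };
      const int* dc = odd ? dc_odd : dc_even;
      for (int c = 0; c < ncol; ++c) {
        int s = r * ncol + c;
        for (int d = 0; d < 6; ++d) {
          int cc = c + dc[d], rr = r + dr[d];
          if (px) cc = (cc % ncol + ncol) % ncol;
          else if (cc < 0 || cc >= ncol) continue;
          if (py) rr = (rr % nrow + nrow) % nrow;
          else if (rr < 0 || rr >= nrow) continue;
          nbr[6 * (size_t)s + d] = rr * ncol + cc;
        }
      }
    }
  }

  int degree(int s) const {
    int k = 0;
    for (int d = 0; d < 6; ++d) if (nbr[6 * (size_t)s + d] >= 0) ++k;
    return k;
  }
};

// breadth-first disk of hex graph distance <= R around `from`
static std::vector<int> bfs_disk(const HexLattice& lat, int from, int R) {
  std::vector<int> out;
  std::vector<int> dist(lat.N(), -1);
  std::queue<int> q;
  dist[from] = 0; q.push(from); out.push_back(from);
  while (!q.empty()) {
    int u = q.front(); q.pop();
    if (dist[u] >= R) continue;
    for (int d = 0; d < 6; ++d) {
      int v = lat.nbr[6 * (size_t)u + d];
      if (v >= 0 && dist[v] < 0) {
        dist[v] = dist[u] + 1; q.push(v); out.push_back(v);
      }
    }
  }
  return out;
}

// Would removing site t disconnect the cell owning it?  Local ring check on
// the cyclic neighbor order; flood fill through the cell when ambiguous.
static bool removal_keeps_connected(const HexLattice& lat,
                                    const std::vector<int>& owner, int t) {
  int b = owner[t];
  int occ[6]; int nocc = 0;
  for (int d = 0; d < 6; ++d) {
    int u = lat.nbr[6 * (size_t)t + d];
    occ[d] = (u >= 0 && u != t && owner[u] == b) ? 1 : 0;
    nocc += occ[d];
  }
  if (nocc == 0) return true;  // last-site removal: nothing left to disconnect
  // count occupied runs around the cycle
  int runs = 0;
  for (int d = 0; d < 6; ++d)
    if (occ[d] == 1 && occ[(d + 5) % 6] == 0) ++runs;
  if (runs <= 1) return true;  // single contiguous arc: provably safe
  // ambiguous: flood fill within the cell avoiding t
  int start = -1;
  for (int d = 0; d < 6; ++d)
    if (occ[d]) { start = lat.nbr[6 * (size_t)t + d]; break; }
  std::vector<int> stack{ start };
  std::unordered_set<int> seen{ start };
  while (!stack.empty()) {
    int u = stack.back(); stack.pop_back();
    for (int d = 0; d < 6; ++d) {
      int v = lat.nbr[6 * (size_t)u + d];
      if (v >= 0 && v != t && owner[v] == b && !seen.count(v)) {
        seen.insert(v); stack.push_back(v);
      }
    }
  }
  for (int d = 0; d < 6; ++d) {
    int u = lat.nbr[6 * (size_t)t + d];
    if (occ[d] && !seen.count(u)) return false;
  }
  return true;
}

// ---------------------------------------------------------------------------
// simulation state

struct Cell {
  bool alive = false;
  int area = 0, perim = 0;
  double sx = 0.0, sy = 0.0;          // sums of unwrapped site coordinates
  std::unordered_set<int> sites;
  int phase = 0;                       // 0 quiescent, 1 growth, 2 division
  int clock = 0;
  double kA = 0, kP = 0, deps = 0;     // effective (cycle-modulated) params
};

struct CPM {
  HexLattice lat;
  // model parameters (single cell type; per-cell effective copies in Cell)
  double kA0 = 0, kP0 = 0, eps0 = 0, deps0 = 0, mu = 0.1;
  double B = 0, dB = 0, D = 0, kBT = 1.0;
  int Rsig = 5;
  double ps2 = 1.0 / 3.0;   // perimeter-unit factor: kP multiplies (ps*E)^2
  bool phi_additive = true;
  bool hastings = true;
  bool feedback_sign = true;           // sign-only vs magnitude-proportional
  // fields
  std::vector<double> phi;
  std::vector<char> forb;
  std::vector<int> owner;              // 0 empty, >0 cell id
  std::vector<double> eps;
  std::vector<int> F;
  std::vector<double> ux, uy;          // unwrapped coords of occupied sites
  std::vector<Cell> cells;             // id-indexed, [0] unused
  // cell cycle
  bool cyc_on = false;
  int Tg = 180, Td = 20;
  double AT = 1.0, Aref = 0.0, exit_rate = 0.0;
  // boundary-pair bookkeeping: key = 6*site + dir
  std::vector<int> live;
  std::vector<int> pos;                // key -> index in live, -1 absent
  long mcs = 0;
  std::mt19937_64 rng;
  // scratch for disk BFS
  std::vector<int> mark;
  int mark_gen = 0;

  double runif() {
    return std::uniform_real_distribution<double>(0.0, 1.0)(rng);
  }
  size_t rint(size_t n) {
    return std::uniform_int_distribution<size_t>(0, n - 1)(rng);
  }

  double eps_eff(int s) const {
    return phi_additive ? eps[s] + phi[s] : eps[s] * phi[s];
  }

  bool pair_valid_with(int s, int d, int t_site, int t_owner) const {
    int t = lat.nbr[6 * (size_t)s + d];
    if (t < 0 || t == s) return false;
    if (forb[s] || forb[t]) return false;
    int a = (s == t_site) ? t_owner : owner[s];
    int b = (t == t_site) ? t_owner : owner[t];
    if (a == b) return false;
    return a > 0 || b > 0;
  }
  bool pair_valid(int s, int d) const { return pair_valid_with(s, d, -1, -1); }

  void pair_sync(int s, int d) {
    int key = 6 * s + d;
    bool valid = pair_valid(s, d);
    int p = pos[key];
    if (valid && p < 0) {
      pos[key] = (int)live.size();
      live.push_back(key);
    } else if (!valid && p >= 0) {
      int lastkey = live.back();
      live[p] = lastkey; pos[lastkey] = p;
      live.pop_back(); pos[key] = -1;
    }
  }

  // revalidate the 12 directed pairs incident to site t
  void rebuild_pairs_at(int t) {
    for (int d = 0; d < 6; ++d) {
      pair_sync(t, d);
      int u = lat.nbr[6 * (size_t)t + d];
      if (u >= 0) pair_sync(u, (d + 3) % 6);
    }
  }

  void rebuild_all_pairs() {
    live.clear();
    std::fill(pos.begin(), pos.end(), -1);
    for (int s = 0; s < lat.N(); ++s)
      for (int d = 0; d < 6; ++d)
        pair_sync(s, d);
  }

  // change in boundary-pair count if owner[t] became `a`
  int pair_count_delta(int t, int a) const {
    int before = 0, after = 0;
    for (int d = 0; d < 6; ++d) {
      before += pair_valid(t, d) ? 1 : 0;
      after  += pair_valid_with(t, d, t, a) ? 1 : 0;
      int u = lat.nbr[6 * (size_t)t + d];
      if (u >= 0) {
        int dd = (d + 3) % 6;
        before += pair_valid(u, dd) ? 1 : 0;
        after  += pair_valid_with(u, dd, t, a) ? 1 : 0;
      }
    }
    return after - before;
  }

  // energy difference of copying owner(s) onto t; breakdown via out-params
  double delta_H(int s, int t, int* created_out = nullptr,
                 int* destroyed_out = nullptr, int* lost_out = nullptr) const {
    int a = owner[s], b = owner[t];
    double dH = 0.0;
    int nA = 0, nB = 0, deg = 0, contacts_a = 0, contacts_b = 0;
    for (int d = 0; d < 6; ++d) {
      int u = lat.nbr[6 * (size_t)t + d];
      if (u < 0) continue;
      ++deg;
      int w = (u == t) ? owner[t] : owner[u];
      if (a > 0 && w == a) ++nA;
      if (b > 0 && w == b) ++nB;
      if (w > 0 && w != a) ++contacts_a;   // cell-cell contacts of t if owned by a
      if (w > 0 && w != b) ++contacts_b;   // cell-cell contacts of t as owned by b
    }
    if (a > 0) {
      const Cell& ca = cells[a];
      double A = ca.area, P = ca.perim;
      int dP = (deg - nA) - nA;
      dH += ca.kA * ((A + 1) * (A + 1) - A * A)
          + ca.kP * ps2 * ((P + dP) * (P + dP) - P * P);
      // conquered site adopts the conqueror's polarization
      double e_new = phi_additive ? eps[s] + phi[t] : eps[s] * phi[t];
      dH -= e_new;
    }
    if (b > 0) {
      const Cell& cb = cells[b];
      double A = cb.area, P = cb.perim;
      int dP = -(deg - nB) + nB;
      dH += cb.kA * ((A - 1) * (A - 1) - A * A)
          + cb.kP * ps2 * ((P + dP) * (P + dP) - P * P);
      dH += eps_eff(t);   // losing the site removes its field contribution
      dH += D;            // cell-substrate dissipation on any lost site
    }
    int created = (a > 0) ? contacts_a : 0;
    int destroyed = (b > 0) ? contacts_b : 0;
    dH += -B * created + (B + dB) * destroyed;
    if (created_out) *created_out = created;
    if (destroyed_out) *destroyed_out = destroyed;
    if (lost_out) *lost_out = (b > 0) ? 1 : 0;
    return dH;
  }

  void apply_move(int s, int t) {
    int a = owner[s], b = owner[t];
    int nA = 0, nB = 0, deg = 0;
    for (int d = 0; d < 6; ++d) {
      int u = lat.nbr[6 * (size_t)t + d];
      if (u < 0) continue;
      ++deg;
      int w = (u == t) ? owner[t] : owner[u];
      if (a > 0 && w == a) ++nA;
      if (b > 0 && w == b) ++nB;
    }
    if (b > 0) {
      Cell& cb = cells[b];
      cb.area -= 1;
      cb.perim += -(deg - nB) + nB;
      cb.sx -= ux[t]; cb.sy -= uy[t];
      cb.sites.erase(t);
    }
    if (a > 0) {
      Cell& ca = cells[a];
      ca.area += 1;
      ca.perim += (deg - nA) - nA;
      // unwrapped coordinate propagates from the source site
      int dsrc = -1;
      for (int d = 0; d < 6; ++d)
        if (lat.nbr[6 * (size_t)s + d] == t) { dsrc = d; break; }
      ux[t] = ux[s] + DIR_DX[dsrc];
      uy[t] = uy[s] + DIR_DY[dsrc];
      ca.sx += ux[t]; ca.sy += uy[t];
      ca.sites.insert(t);
      owner[t] = a;
      eps[t] = eps[s];
      F[t] = 0;  // conquered sites start with a neutral accumulator
    } else {
      owner[t] = 0; eps[t] = 0.0; F[t] = 0;
    }
    rebuild_pairs_at(t);
  }

  // feedback of an accepted event centered on the changed site t
  void record_feedback(int a, int b, int t) {
    if (Rsig < 0) return;
    if (++mark_gen == INT32_MAX) { std::fill(mark.begin(), mark.end(), 0); mark_gen = 1; }
    // BFS disk with depth bound
    std::vector<std::pair<int,int>> q; q.reserve(1 + 3 * Rsig * (Rsig + 1));
    q.emplace_back(t, 0); mark[t] = mark_gen;
    size_t head = 0;
    while (head < q.size()) {
      auto [u, du] = q[head++];
      int w = owner[u];
      if (a > 0 && w == a) F[u] += 1;
      if (b > 0 && w == b) F[u] -= 1;
      if (du >= Rsig) continue;
      for (int d = 0; d < 6; ++d) {
        int v = lat.nbr[6 * (size_t)u + d];
        if (v >= 0 && mark[v] != mark_gen) { mark[v] = mark_gen; q.emplace_back(v, du + 1); }
      }
    }
  }

  void update_polarization() {
    for (int s = 0; s < lat.N(); ++s) {
      int c = owner[s];
      if (c <= 0) { F[s] = 0; continue; }
      double dc = cells[c].deps;
      double target, rate = mu;
      if (F[s] > 0) target = eps0 + 0.5 * dc;
      else if (F[s] < 0) target = eps0 - 0.5 * dc;
      else target = eps0;
      if (!feedback_sign && F[s] != 0)
        rate = std::min(1.0, mu * std::abs((double)F[s]));
      eps[s] += rate * (target - eps[s]);
      F[s] = 0;
    }
  }

  void set_growth_params(Cell& c) {
    double f = 1.0 - 0.5 * (double)c.clock / (double)Tg;
    c.kA = kA0 * f;
    c.kP = kP0 * std::sqrt(f);
  }

  void split_cell(int id);

  void update_cycles() {
    int ncell = (int)cells.size();
    for (int id = 1; id < ncell; ++id) {
      Cell& c = cells[id];
      if (!c.alive) continue;
      if (c.phase == 0) {
        bool go = c.area > AT * Aref;
        if (!go && exit_rate > 0 && runif() < exit_rate) go = true;
        if (go) { c.phase = 1; c.clock = 0; set_growth_params(c); }
      } else if (c.phase == 1) {
        c.clock += 1;
        set_growth_params(c);
        if (c.clock >= Tg) { c.phase = 2; c.clock = 0; c.deps = 0.0; }
      } else {
        c.clock += 1;
        if (c.clock >= Td) {
          if (c.area >= 2) split_cell(id);
          // else: division deferred to a later MCS
        }
      }
    }
  }

  void run_mcs() {
    size_t n_att = live.size();
    for (size_t i = 0; i < n_att && !live.empty(); ++i) {
      int key = live[rint(live.size())];
      int s = key / 6, d = key % 6;
      int t = lat.nbr[6 * (size_t)s + d];
      int a = owner[s], b = owner[t];
      if (b > 0) {
        if (cells[b].area <= 1) continue;                    // no annihilation
        if (!removal_keeps_connected(lat, owner, t)) continue;
      }
      double dH = delta_H(s, t);
      double logp = -dH / kBT;
      if (hastings) {
        int Bnow = (int)live.size();
        int Bafter = Bnow + pair_count_delta(t, a);
        if (Bafter > 0) logp += std::log((double)Bnow / (double)Bafter);
      }
      if (logp < 0.0 && runif() >= std::exp(logp)) continue;
      apply_move(s, t);
      record_feedback(a, b, t);
    }
    update_polarization();
    if (cyc_on) update_cycles();
    mcs += 1;
  }

  double total_H() const {
    double H = 0.0;
    for (size_t id = 1; id < cells.size(); ++id) {
      const Cell& c = cells[id];
      if (!c.alive) continue;
      // recount perimeter from scratch
      long P = 0;
      for (int u : c.sites)
        for (int d = 0; d < 6; ++d) {
          int v = lat.nbr[6 * (size_t)u + d];
          if (v >= 0 && owner[v] != (int)id) ++P;
        }
      H += c.kA * (double)c.area * (double)c.area + c.kP * ps2 * (double)P * (double)P;
    }
    long contacts2 = 0;  // directed cell-cell contacts (counted twice)
    for (int s = 0; s < lat.N(); ++s) {
      if (owner[s] > 0) H -= eps_eff(s);
      for (int d = 0; d < 6; ++d) {
        int v = lat.nbr[6 * (size_t)s + d];
        if (v >= 0 && owner[s] > 0 && owner[v] > 0 && owner[v] != owner[s])
          ++contacts2;
      }
    }
    H += -B * 0.5 * (double)contacts2;
    return H;
  }
};

// split a dividing mother along the line through its center of mass
// perpendicular to the gyration-tensor major axis
static void split_sites_by_axis(const std::vector<int>& sites,
                                const std::vector<double>& ux,
                                const std::vector<double>& uy,
                                const HexLattice& lat,
                                std::vector<int>& d1, std::vector<int>& d2) {
  int n = (int)sites.size();
  double mx = 0, my = 0;
  for (int s : sites) { mx += ux[s]; my += uy[s]; }
  mx /= n; my /= n;
  double sxx = 0, sxy = 0, syy = 0;
  for (int s : sites) {
    double dx = ux[s] - mx, dy = uy[s] - my;
    sxx += dx * dx; sxy += dx * dy; syy += dy * dy;
  }
  sxx /= n; sxy /= n; syy /= n;
  // leading eigenvector of [[sxx,sxy],[sxy,syy]]
  double tr = sxx + syy, det = sxx * syy - sxy * sxy;
  double l1 = 0.5 * tr + std::sqrt(std::max(0.0, 0.25 * tr * tr - det));
  double ex, ey;
  if (std::abs(sxy) > 1e-12) { ex = l1 - syy; ey = sxy; }
  else if (sxx >= syy) { ex = 1; ey = 0; }
  else { ex = 0; ey = 1; }
  double nrm = std::hypot(ex, ey);
  ex /= nrm; ey /= nrm;
  // projections onto the major axis
  std::vector<std::pair<double,int>> proj(n);
  for (int i = 0; i < n; ++i) {
    int s = sites[i];
    proj[i] = { (ux[s] - mx) * ex + (uy[s] - my) * ey, s };
  }
  std::unordered_set<int> mother(sites.begin(), sites.end());
  std::unordered_map<int,double> pmap;
  for (auto& pr : proj) pmap[pr.second] = pr.first;
  // connected greedy growth of daughter 1 from the high-projection extreme,
  // always absorbing the reachable site with the largest projection
  int seed = std::max_element(proj.begin(), proj.end())->second;
  int k = n / 2;
  std::priority_queue<std::pair<double,int>> heap;
  std::unordered_set<int> in1, pushed;
  heap.push({ pmap[seed], seed }); pushed.insert(seed);
  while ((int)in1.size() < k && !heap.empty()) {
    auto [p, s] = heap.top(); heap.pop();
    in1.insert(s);
    for (int d = 0; d < 6; ++d) {
      int v = lat.nbr[6 * (size_t)s + d];
      if (v >= 0 && mother.count(v) && !pushed.count(v)) {
        pushed.insert(v);
        heap.push({ pmap[v], v });
      }
    }
  }
  // remainder is daughter 2; reassign stray components (those not containing
  // the low-projection extreme) back to daughter 1 to keep both connected
  std::vector<int> rest;
  for (int s : sites) if (!in1.count(s)) rest.push_back(s);
  if (!rest.empty()) {
    int seed2 = rest[0]; double pmin = pmap[rest[0]];
    for (int s : rest) if (pmap[s] < pmin) { pmin = pmap[s]; seed2 = s; }
    std::unordered_set<int> in2, rset(rest.begin(), rest.end());
    std::vector<int> stack{ seed2 }; in2.insert(seed2);
    while (!stack.empty()) {
      int u = stack.back(); stack.pop_back();
      for (int d = 0; d < 6; ++d) {
        int v = lat.nbr[6 * (size_t)u + d];
        if (v >= 0 && rset.count(v) && !in2.count(v)) { in2.insert(v); stack.push_back(v); }
      }
    }
    for (int s : rest)
      if (!in2.count(s)) in1.insert(s);
    d2.assign(in2.begin(), in2.end());
  }
  d1.assign(in1.begin(), in1.end());
  if (d2.empty()) {  // degenerate: give daughter 2 one boundary site
    // move the lowest-projection site of d1 whose removal keeps d1 connected
    std::sort(d1.begin(), d1.end(), [&](int a, int b){ return pmap[a] < pmap[b]; });
    d2.push_back(d1.front());
    d1.erase(d1.begin());
  }
}

void CPM::split_cell(int id) {
  Cell& mom = cells[id];
  std::vector<int> msites(mom.sites.begin(), mom.sites.end());
  std::vector<int> d1, d2;
  split_sites_by_axis(msites, ux, uy, lat, d1, d2);
  int id2 = (int)cells.size();
  cells.push_back(Cell());
  Cell& mother = cells[id];          // re-reference after push_back
  Cell& dau = cells[id2];
  dau.alive = true;
  for (int s : d2) owner[s] = id2;
  // re-initialize both daughters: quiescent, unpolarized, base parameters
  auto reinit = [&](Cell& c, const std::vector<int>& ss, int cid) {
    c.sites.clear();
    c.area = (int)ss.size();
    c.perim = 0; c.sx = 0; c.sy = 0;
    c.phase = 0; c.clock = 0;
    c.kA = kA0; c.kP = kP0; c.deps = deps0;
    for (int s : ss) {
      c.sites.insert(s);
      c.sx += ux[s]; c.sy += uy[s];
      eps[s] = eps0; F[s] = 0;
      for (int d = 0; d < 6; ++d) {
        int v = lat.nbr[6 * (size_t)s + d];
        if (v >= 0 && owner[v] != cid) ++c.perim;
      }
    }
  };
  reinit(mother, d1, id);
  reinit(dau, d2, id2);
  for (int s : msites) rebuild_pairs_at(s);
}

// ---------------------------------------------------------------------------
// exported standalone hex-lattice utilities (1-based sites on the R side)

// [[Rcpp::export]]
IntegerMatrix hex_neighbors_cpp(int ncol, int nrow, bool px, bool py) {
  HexLattice lat; lat.build(ncol, nrow, px, py);
  IntegerMatrix out(lat.N(), 6);
  for (int s = 0; s < lat.N(); ++s)
    for (int d = 0; d < 6; ++d) {
      int v = lat.nbr[6 * (size_t)s + d];
      out(s, d) = (v < 0) ? NA_INTEGER : v + 1;
    }
  return out;
}

// [[Rcpp::export]]
NumericMatrix hex_coords_cpp(int ncol, int nrow) {
  HexLattice lat; lat.build(ncol, nrow, false, false);
  NumericMatrix out(lat.N(), 2);
  for (int s = 0; s < lat.N(); ++s) { out(s,0) = lat.xcoord(s); out(s,1) = lat.ycoord(s); }
  return out;
}

// [[Rcpp::export]]
IntegerVector hex_disk_cpp(int ncol, int nrow, bool px, bool py, int site, int R) {
  if (R < 0) stop("disk radius must be non-negative");
  HexLattice lat; lat.build(ncol, nrow, px, py);
  if (site < 1 || site > lat.N()) stop("site off lattice");
  std::vector<int> d = bfs_disk(lat, site - 1, R);
  IntegerVector out(d.size());
  for (size_t i = 0; i < d.size(); ++i) out[i] = d[i] + 1;
  return out.sort();
}

// [[Rcpp::export]]
bool conn_check_cpp(IntegerVector owner1, int ncol, int nrow, bool px, bool py,
                    int site) {
  HexLattice lat; lat.build(ncol, nrow, px, py);
  if (site < 1 || site > lat.N()) stop("site off lattice");
  std::vector<int> own(owner1.begin(), owner1.end());
  if (own[site - 1] <= 0) stop("site is not owned by a cell");
  return removal_keeps_connected(lat, own, site - 1);
}

// [[Rcpp::export]]
List hex_split_cpp(int ncol, int nrow, bool px, bool py, IntegerVector sites1) {
  HexLattice lat; lat.build(ncol, nrow, px, py);
  int n = sites1.size();
  if (n < 2) stop("need at least 2 sites to split");
  std::vector<int> sites(n);
  for (int i = 0; i < n; ++i) sites[i] = sites1[i] - 1;
  // unwrap coordinates by BFS through the site set
  std::vector<double> ux(lat.N(), 0), uy(lat.N(), 0);
  std::unordered_set<int> sset(sites.begin(), sites.end());
  std::unordered_set<int> seen;
  std::vector<int> stack{ sites[0] };
  seen.insert(sites[0]);
  ux[sites[0]] = lat.xcoord(sites[0]); uy[sites[0]] = lat.ycoord(sites[0]);
  while (!stack.empty()) {
    int u = stack.back(); stack.pop_back();
    for (int d = 0; d < 6; ++d) {
      int v = lat.nbr[6 * (size_t)u + d];
      if (v >= 0 && sset.count(v) && !seen.count(v)) {
        seen.insert(v);
        ux[v] = ux[u] + DIR_DX[d]; uy[v] = uy[u] + DIR_DY[d];
        stack.push_back(v);
      }
    }
  }
  if (seen.size() != sset.size()) stop("site set is not connected");
  std::vector<int> d1, d2;
  split_sites_by_axis(sites, ux, uy, lat, d1, d2);
  IntegerVector o1(d1.size()), o2(d2.size());
  for (size_t i = 0; i < d1.size(); ++i) o1[i] = d1[i] + 1;
  for (size_t i = 0; i < d2.size(); ++i) o2[i] = d2[i] + 1;
  return List::create(_["first"] = o1.sort(), _["second"] = o2.sort());
}

// ---------------------------------------------------------------------------
// engine API

static CPM* get(SEXP xp) {
  Rcpp::XPtr<CPM> p(xp);
  return p.get();
}

// [[Rcpp::export]]
SEXP cpm_create_cpp(List cfg) {
  CPM* m = new CPM();
  Rcpp::XPtr<CPM> xp(m, true);
  m->lat.build(as<int>(cfg["ncol"]), as<int>(cfg["nrow"]),
               as<bool>(cfg["periodic_x"]), as<bool>(cfg["periodic_y"]));
  int N = m->lat.N();
  m->kA0 = as<double>(cfg["kappa_A"]); m->kP0 = as<double>(cfg["kappa_P"]);
  m->eps0 = as<double>(cfg["eps0"]);   m->deps0 = as<double>(cfg["delta_eps"]);
  m->Rsig = as<int>(cfg["R"]);         m->mu = as<double>(cfg["mu"]);
  m->B = as<double>(cfg["B"]);         m->dB = as<double>(cfg["delta_B"]);
  m->D = as<double>(cfg["D"]);         m->kBT = as<double>(cfg["kBT"]);
  m->phi_additive = as<std::string>(cfg["phi_mode"]) != "multiplicative";
  m->ps2 = (as<std::string>(cfg["perimeter_unit"]) == "edges") ? 1.0 : 1.0 / 3.0;
  m->hastings = as<bool>(cfg["hastings"]);
  m->feedback_sign = as<std::string>(cfg["feedback"]) != "magnitude";
  NumericVector phi = cfg["phi"];
  LogicalVector fb = cfg["forbidden"];
  if (phi.size() != N || fb.size() != N) stop("phi/forbidden length mismatch");
  m->phi.assign(phi.begin(), phi.end());
  m->forb.assign(N, 0);
  for (int i = 0; i < N; ++i) m->forb[i] = fb[i] ? 1 : 0;
  m->owner.assign(N, 0);
  m->eps.assign(N, 0.0);
  m->F.assign(N, 0);
  m->ux.assign(N, 0.0); m->uy.assign(N, 0.0);
  m->mark.assign(N, 0);
  m->pos.assign(6 * (size_t)N, -1);
  List cycle = cfg["cycle"];
  m->cyc_on = as<bool>(cycle["enabled"]);
  if (m->cyc_on) {
    m->Tg = as<int>(cycle["Tg"]); m->Td = as<int>(cycle["Td"]);
    m->AT = as<double>(cycle["A_T"]); m->Aref = as<double>(cycle["A_ref"]);
    m->exit_rate = as<double>(cycle["exit_rate"]);
    if (m->Tg <= 0 || m->Td <= 0 || m->AT <= 0 || m->Aref <= 0)
      stop("cycle parameters must be positive");
  }
  m->rng.seed((uint64_t)as<double>(cfg["seed"]));
  // seed cells
  List cells = cfg["cells"];
  m->cells.resize(cells.size() + 1);
  for (int ci = 0; ci < cells.size(); ++ci) {
    IntegerVector ss = cells[ci];
    int id = ci + 1;
    Cell& c = m->cells[id];
    c.alive = true;
    c.kA = m->kA0; c.kP = m->kP0; c.deps = m->deps0;
    for (int i = 0; i < ss.size(); ++i) {
      int s = ss[i] - 1;
      if (s < 0 || s >= N) stop("cell site off lattice");
      if (m->forb[s]) stop("cell placed on a forbidden site");
      if (m->owner[s] != 0) stop("overlapping cell placements");
      m->owner[s] = id;
      c.sites.insert(s);
    }
    c.area = (int)c.sites.size();
    if (c.area == 0) stop("empty cell in placement");
    // unwrap coordinates via BFS through the cell
    int s0 = *c.sites.begin();
    std::vector<int> stack{ s0 };
    std::unordered_set<int> seen{ s0 };
    m->ux[s0] = m->lat.xcoord(s0); m->uy[s0] = m->lat.ycoord(s0);
    while (!stack.empty()) {
      int u = stack.back(); stack.pop_back();
      for (int d = 0; d < 6; ++d) {
        int v = m->lat.nbr[6 * (size_t)u + d];
        if (v >= 0 && c.sites.count(v) && !seen.count(v)) {
          seen.insert(v);
          m->ux[v] = m->ux[u] + DIR_DX[d];
          m->uy[v] = m->uy[u] + DIR_DY[d];
          stack.push_back(v);
        }
      }
    }
    if (seen.size() != c.sites.size()) stop("cell site set is not connected");
    c.perim = 0; c.sx = 0; c.sy = 0;
    for (int s : c.sites) {
      m->eps[s] = m->eps0;
      c.sx += m->ux[s]; c.sy += m->uy[s];
      for (int d = 0; d < 6; ++d) {
        int v = m->lat.nbr[6 * (size_t)s + d];
        if (v >= 0 && m->owner[v] != id) ++c.perim;
      }
    }
  }
  m->rebuild_all_pairs();
  return xp;
}

// [[Rcpp::export]]
void cpm_run_cpp(SEXP xp, int n_mcs) {
  CPM* m = get(xp);
  for (int i = 0; i < n_mcs; ++i) m->run_mcs();
}

// [[Rcpp::export]]
List cpm_state_cpp(SEXP xp) {
  CPM* m = get(xp);
  int N = m->lat.N();
  IntegerVector owner(N), F(N);
  NumericVector eps(N);
  for (int i = 0; i < N; ++i) { owner[i] = m->owner[i]; eps[i] = m->eps[i]; F[i] = m->F[i]; }
  return List::create(_["owner"] = owner, _["eps"] = eps, _["F"] = F,
                      _["mcs"] = (double)m->mcs,
                      _["n_pairs"] = (int)m->live.size(),
                      _["ps2"] = m->ps2);
}

// [[Rcpp::export]]
DataFrame cpm_cells_cpp(SEXP xp) {
  CPM* m = get(xp);
  std::vector<int> id, area, perim, phase, clock;
  std::vector<double> x, y, meps, kA, kP, deps;
  for (size_t i = 1; i < m->cells.size(); ++i) {
    const Cell& c = m->cells[i];
    if (!c.alive) continue;
    id.push_back((int)i);
    area.push_back(c.area); perim.push_back(c.perim);
    phase.push_back(c.phase); clock.push_back(c.clock);
    x.push_back(c.sx / c.area); y.push_back(c.sy / c.area);
    double s = 0; for (int u : c.sites) s += m->eps[u];
    meps.push_back(s / c.area);
    kA.push_back(c.kA); kP.push_back(c.kP); deps.push_back(c.deps);
  }
  return DataFrame::create(_["cell"] = id, _["area"] = area,
                           _["perimeter"] = perim, _["x"] = x, _["y"] = y,
                           _["phase"] = phase, _["clock"] = clock,
                           _["mean_eps"] = meps, _["kappa_A_eff"] = kA,
                           _["kappa_P_eff"] = kP, _["delta_eps_eff"] = deps);
}

// [[Rcpp::export]]
double cpm_total_energy_cpp(SEXP xp) { return get(xp)->total_H(); }

// [[Rcpp::export]]
DataFrame cpm_pairs_cpp(SEXP xp) {
  CPM* m = get(xp);
  int n = (int)m->live.size();
  IntegerVector src(n), tgt(n);
  for (int i = 0; i < n; ++i) {
    int key = m->live[i];
    int s = key / 6, d = key % 6;
    src[i] = s + 1;
    tgt[i] = m->lat.nbr[6 * (size_t)s + d] + 1;
  }
  return DataFrame::create(_["source"] = src, _["target"] = tgt);
}

// [[Rcpp::export]]
List cpm_delta_cpp(SEXP xp, int s1, int t1) {
  CPM* m = get(xp);
  int s = s1 - 1, t = t1 - 1;
  if (s < 0 || s >= m->lat.N() || t < 0 || t >= m->lat.N()) stop("site off lattice");
  bool adjacent = false;
  for (int d = 0; d < 6; ++d) if (m->lat.nbr[6 * (size_t)s + d] == t) adjacent = true;
  if (!adjacent) stop("source and target are not lattice neighbors");
  if (m->owner[s] == m->owner[t]) stop("source and target share the same owner");
  int created, destroyed, lost;
  double dH = m->delta_H(s, t, &created, &destroyed, &lost);
  return List::create(_["dH"] = dH,
                      _["dH_state"] = dH - m->dB * destroyed - m->D * lost,
                      _["created"] = created, _["destroyed"] = destroyed,
                      _["lost"] = lost);
}

// [[Rcpp::export]]
void cpm_apply_cpp(SEXP xp, int s1, int t1, bool feedback) {
  CPM* m = get(xp);
  int s = s1 - 1, t = t1 - 1;
  if (m->owner[s] == m->owner[t]) stop("invalid move: same owner");
  int b = m->owner[t];
  if (b > 0) {
    if (m->cells[b].area <= 1) stop("move would annihilate a cell");
    if (!removal_keeps_connected(m->lat, m->owner, t))
      stop("move would fragment a cell");
  }
  int a = m->owner[s];
  m->apply_move(s, t);
  if (feedback) m->record_feedback(a, b, t);
}

// [[Rcpp::export]]
void cpm_update_polarization_cpp(SEXP xp) { get(xp)->update_polarization(); }

// [[Rcpp::export]]
void cpm_set_eps_cpp(SEXP xp, NumericVector v) {
  CPM* m = get(xp);
  if (v.size() != m->lat.N()) stop("length mismatch");
  for (int i = 0; i < v.size(); ++i) m->eps[i] = v[i];
}

// [[Rcpp::export]]
void cpm_set_F_cpp(SEXP xp, IntegerVector v) {
  CPM* m = get(xp);
  if (v.size() != m->lat.N()) stop("length mismatch");
  for (int i = 0; i < v.size(); ++i) m->F[i] = v[i];
}

// [[Rcpp::export]]
void cpm_clear_forbidden_cpp(SEXP xp) {
  CPM* m = get(xp);
  std::fill(m->forb.begin(), m->forb.end(), 0);
  std::fill(m->phi.begin(), m->phi.end(), 0.0);
  m->rebuild_all_pairs();
}

// [[Rcpp::export]]
List cpm_audit_cpp(SEXP xp) {
  CPM* m = get(xp);
  std::vector<std::string> msg;
  // ownership consistency and cache recounts
  std::vector<long> area(m->cells.size(), 0);
  for (int s = 0; s < m->lat.N(); ++s) {
    int o = m->owner[s];
    if (o > 0) {
      if (o >= (int)m->cells.size() || !m->cells[o].alive)
        msg.push_back("site owned by a dead cell");
      else {
        ++area[o];
        if (!m->cells[o].sites.count(s)) msg.push_back("site missing from cell set");
      }
      if (m->forb[s]) msg.push_back("cell occupies a forbidden site");
    }
  }
  for (size_t id = 1; id < m->cells.size(); ++id) {
    const Cell& c = m->cells[id];
    if (!c.alive) continue;
    if (area[id] != c.area) msg.push_back("cached area mismatch");
    if ((int)c.sites.size() != c.area) msg.push_back("site-set size mismatch");
    long P = 0; double sx = 0, sy = 0;
    for (int u : c.sites) {
      sx += m->ux[u]; sy += m->uy[u];
      for (int d = 0; d < 6; ++d) {
        int v = m->lat.nbr[6 * (size_t)u + d];
        if (v >= 0 && m->owner[v] != (int)id) ++P;
      }
    }
    if (P != c.perim) msg.push_back("cached perimeter mismatch");
    if (std::abs(sx - c.sx) > 1e-6 || std::abs(sy - c.sy) > 1e-6)
      msg.push_back("cached center-of-mass sum mismatch");
    // connectivity from scratch
    std::unordered_set<int> seen;
    std::vector<int> stack{ *c.sites.begin() };
    seen.insert(*c.sites.begin());
    while (!stack.empty()) {
      int u = stack.back(); stack.pop_back();
      for (int d = 0; d < 6; ++d) {
        int v = m->lat.nbr[6 * (size_t)u + d];
        if (v >= 0 && c.sites.count(v) && !seen.count(v)) { seen.insert(v); stack.push_back(v); }
      }
    }
    if (seen.size() != c.sites.size()) msg.push_back("cell is fragmented");
    // polarization bounds
    for (int u : c.sites) {
      double lo = m->eps0 - 0.5 * std::max(m->deps0, c.deps) - 1e-9;
      double hi = m->eps0 + 0.5 * std::max(m->deps0, c.deps) + 1e-9;
      if (m->eps[u] < lo || m->eps[u] > hi) { msg.push_back("polarization out of bounds"); break; }
    }
  }
  // boundary-pair set from scratch
  long nvalid = 0;
  for (int s = 0; s < m->lat.N(); ++s)
    for (int d = 0; d < 6; ++d) {
      bool valid = m->pair_valid(s, d);
      nvalid += valid ? 1 : 0;
      bool inset = m->pos[6 * s + d] >= 0;
      if (valid != inset) { msg.push_back("boundary-pair set mismatch"); }
    }
  if (nvalid != (long)m->live.size()) msg.push_back("boundary-pair count mismatch");
  return List::create(_["ok"] = msg.empty(), _["messages"] = wrap(msg));
}
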