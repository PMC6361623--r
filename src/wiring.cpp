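// Cell placement and stochastic distance-dependent wiring.
// All randomness comes from a dedicated seeded stream, independent of R's
// RNG; candidate pairs are enumerated in a fixed order so realizations are
// reproducible.  Neighbor searches use a uniform-grid spatial index.

#include <Rcpp.h>
#include "rng.h"

using namespace Rcpp;
using namespace blg;

namespace {

struct Grid {
  double cell, box;
  int nb;
  std::vector<std::vector<int>> bins;
  Grid(double box_, double cell_) : cell(cell_), box(box_) {
    nb = std::max(1, (int)(box_ / cell_));
    bins.assign((size_t)nb * nb * nb, {});
  }
  inline int idx(double x) const {
    int i = (int)(x / cell);
    if (i < 0) i = 0;
    if (i >= nb) i = nb - 1;
    return i;
  }
  inline size_t bin(double x, double y, double z) const {
    return ((size_t)idx(x) * nb + idx(y)) * nb + idx(z);
  }
  void insert(int id, double x, double y, double z) {
    bins[bin(x, y, z)].push_back(id);
  }
  template <class F>
  void neighbors(double x, double y, double z, double radius, F f) const {
    int r = (int)(radius / cell) + 1;
    int ix = idx(x), iy = idx(y), iz = idx(z);
    for (int a = std::max(0, ix - r); a <= std::min(nb - 1, ix + r); ++a)
      for (int b = std::max(0, iy - r); b <= std::min(nb - 1, iy + r); ++b)
        for (int c = std::max(0, iz - r); c <= std::min(nb - 1, iz + r); ++c)
          for (int id : bins[((size_t)a * nb + b) * nb + c]) f(id);
  }
};

inline double dist3(const NumericMatrix &p, int i, int j) {
  double dx = p(i, 0) - p(j, 0), dy = p(i, 1) - p(j, 1), dz = p(i, 2) - p(j, 2);
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

} // namespace

// [[Rcpp::export]]
NumericMatrix cpp_place_cells(int n, double box, double min_dist, double seed,
                              int max_tries) {
  Rng rng; rng.seed((uint64_t)seed, 0xB10C0DE);
  NumericMatrix pos(n, 3);
  Grid grid(box, std::max(min_dist, box / 64.0));
  double d2 = min_dist * min_dist;
  long tries = 0, budget = (long)max_tries * (long)n;
  for (int i = 0; i < n; ++i) {
    for (;;) {
      if (++tries > budget)
        stop("cell placement infeasible: minimum spacing %.1f um too large for %d cells", min_dist, n);
      double x = rng.unif() * box, y = rng.unif() * box, z = rng.unif() * box;
      bool ok = true;
      grid.neighbors(x, y, z, min_dist, [&](int id) {
        if (!ok) return;
        double dx = pos(id, 0) - x, dy = pos(id, 1) - y, dz = pos(id, 2) - z;
        if (dx * dx + dy * dy + dz * dz <= d2) ok = false;
      });
      if (ok) {
        pos(i, 0) = x; pos(i, 1) = y; pos(i, 2) = z;
        grid.insert(i, x, y, z);
        break;
      }
    }
  }
  return pos;
}

// types: 0 = PN_A, 1 = PN_C, 2 = FSI (0-based cell ids in the output).
// Returns directed chemical edges (src, dst, kind, dist) and symmetric
// electrical pairs.  kind: 1 PN->PN, 2 PN->FSI, 3 FSI->PN, 4 FSI->FSI.
// [[Rcpp::export]]
List cpp_wire_intrinsic(NumericMatrix pos, IntegerVector types,
                        NumericVector pnpn_breaks, NumericVector pnpn_prob,
                        double fsi_range,
                        double p_fsi2pn, double p_pn2fsi, double p_recip,
                        double p_elec, double p_cu, double p_cb,
                        double p_uu, double p_ub,
                        double box, double seed) {
  const int n = pos.nrow();
  Rng rng; rng.seed((uint64_t)seed, 0x77112233);
  double pn_range = pnpn_breaks[pnpn_breaks.size() - 1];

  Grid grid(box, 100.0);
  for (int i = 0; i < n; ++i) grid.insert(i, pos(i, 0), pos(i, 1), pos(i, 2));

  std::vector<int> src, dst, kind;
  std::vector<double> dist;
  std::vector<int> ga, gb;
  std::vector<int> nb;

  auto push = [&](int s, int d, int k, double di) {
    src.push_back(s); dst.push_back(d); kind.push_back(k); dist.push_back(di);
  };

  for (int i = 0; i < n; ++i) {
    nb.clear();
    double range = (types[i] == 2) ? fsi_range : std::max(pn_range, fsi_range);
    grid.neighbors(pos(i, 0), pos(i, 1), pos(i, 2), range,
                   [&](int id) { if (id > i) nb.push_back(id); });
    std::sort(nb.begin(), nb.end());
    for (int j : nb) {
      double d = dist3(pos, i, j);
      bool i_pn = types[i] != 2, j_pn = types[j] != 2;
      if (i_pn && j_pn) {
        if (d > pn_range) continue;
        // distance-binned, independent per direction
        double p = 0.0;
        for (int b = 0; b < pnpn_prob.size(); ++b)
          if (d > pnpn_breaks[b] && d <= pnpn_breaks[b + 1]) { p = pnpn_prob[b]; break; }
        if (d <= pnpn_breaks[0]) p = pnpn_prob[0];
        if (rng.unif() < p) push(i, j, 1, d);
        if (rng.unif() < p) push(j, i, 1, d);
      } else if (i_pn != j_pn) {
        if (d > fsi_range) continue;
        int pn = i_pn ? i : j, fsi = i_pn ? j : i;
        double u = rng.unif();
        if (u < p_fsi2pn) push(fsi, pn, 3, d);
        else if (u < p_fsi2pn + p_pn2fsi) push(pn, fsi, 2, d);
        else if (u < p_fsi2pn + p_pn2fsi + p_recip) {
          push(fsi, pn, 3, d); push(pn, fsi, 2, d);
        }
      } else {
        if (d > fsi_range) continue;
        bool coupled = rng.unif() < p_elec;
        if (coupled) { ga.push_back(i); gb.push_back(j); }
        double pu = coupled ? p_cu : p_uu, pb = coupled ? p_cb : p_ub;
        double u = rng.unif();
        if (u < pu) {
          if (rng.unif() < 0.5) push(i, j, 4, d); else push(j, i, 4, d);
        } else if (u < pu + pb) {
          push(i, j, 4, d); push(j, i, 4, d);
        }
      }
    }
  }

  return List::create(
    _["src"] = wrap(src), _["dst"] = wrap(dst), _["kind"] = wrap(kind),
    _["dist"] = wrap(dist), _["gap_a"] = wrap(ga), _["gap_b"] = wrap(gb));
}

// Each afferent targets n_targets PNs drawn uniformly without replacement,
// plus each FSI lying within `range` of any targeted PN with probability
// p_fsi (independent per afferent-FSI pair over the union neighborhood).
// [[Rcpp::export]]
List cpp_wire_afferents(NumericMatrix pos, IntegerVector types, int n_aff,
                        int n_targets, double p_fsi, double range,
                        double box, double seed) {
  const int n = pos.nrow();
  Rng rng; rng.seed((uint64_t)seed, 0xAFFE0123);
  std::vector<int> pn_ids, fsi_ids;
  for (int i = 0; i < n; ++i) (types[i] == 2 ? fsi_ids : pn_ids).push_back(i);
  const int npn = (int)pn_ids.size();
  if (n_targets > npn) stop("more afferent targets than PNs");

  Grid grid(box, 100.0);
  for (int id : fsi_ids) grid.insert(id, pos(id, 0), pos(id, 1), pos(id, 2));

  std::vector<int> a_src, a_dst;
  std::vector<uint8_t> mark(n, 0);
  std::vector<int> cand;
  for (int a = 0; a < n_aff; ++a) {
    // rejection draw of distinct targets (n_targets << npn)
    std::vector<int> chosen;
    chosen.reserve(n_targets);
    while ((int)chosen.size() < n_targets) {
      int j = (int)(rng.unif() * npn);
      if (j >= npn) j = npn - 1;
      int id = pn_ids[j];
      if (!mark[id]) { mark[id] = 1; chosen.push_back(id); }
    }
    for (int id : chosen) mark[id] = 0;
    cand.clear();
    for (int id : chosen) {
      a_src.push_back(a); a_dst.push_back(id);
      grid.neighbors(pos(id, 0), pos(id, 1), pos(id, 2), range, [&](int f) {
        double dx = pos(f, 0) - pos(id, 0), dy = pos(f, 1) - pos(id, 1),
               dz = pos(f, 2) - pos(id, 2);
        if (dx * dx + dy * dy + dz * dz <= range * range && !mark[f]) {
          mark[f] = 1; cand.push_back(f);
        }
      });
    }
    std::sort(cand.begin(), cand.end());
    for (int f : cand) {
      mark[f] = 0;
      if (rng.unif() < p_fsi) { a_src.push_back(a); a_dst.push_back(f); }
    }
  }
  return List::create(_["aff"] = wrap(a_src), _["dst"] = wrap(a_dst));
}
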