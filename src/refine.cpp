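#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <array>
#include <cstdint>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

namespace {

struct V3 { double x, y, z; };

inline uint64_t ekey(uint32_t a, uint32_t b) {
  if (a > b) std::swap(a, b);
  return (static_cast<uint64_t>(a) << 32) | b;
}

inline double dist2(const V3 &p, const V3 &q) {
  double dx = p.x - q.x, dy = p.y - q.y, dz = p.z - q.z;
  return dx * dx + dy * dy + dz * dz;
}

} // namespace

// Adaptive bisection of a Kuhn-triangulated tetrahedral mesh towards a
// tip-centred size field, using Maubach's newest-vertex bisection.  Each
// tet carries a level l; its refinement edge is (v0, vk) with
// k = 3 - (l mod 3), and bisection at midpoint z yields the two level
// (l+1) children
//   C1 = (v0, ..., v_{k-1}, z, v_{k+1}, ..., v3)
//   C2 = (v1, ..., vk, z, v_{k+1}, ..., v3).
// For meshes whose level-0 elements are consistently ordered Kuhn
// simplices this refinement is conforming and terminates.  A tet is
// bisected when (a) any of its edges already carries a midpoint in the
// global edge table (conformity closure), or (b) its longest edge exceeds
// the local size limit
//   h(x) = tip_edge                          within soi_radius of a tip
//   h(x) = tip_edge + grade_slope * (d-soi)  outside (d = distance to tip).
// The "near" test uses a conservative lower bound on the tip-to-element
// distance (centroid distance minus the largest vertex-centroid radius),
// which covers every element intersecting the sphere of influence, so
// the refinement constraint is guaranteed for intersecting elements.
// Fully deterministic: fixed iteration order.
// [[Rcpp::export(name = ".refine_tets_cpp")]]
List refine_tets_cpp(NumericMatrix V0, IntegerMatrix T0, NumericMatrix tips,
                     double tip_edge, double soi_radius, double grade_slope,
                     int max_pass, bool verbose = false) {
  const R_xlen_t nv0 = V0.nrow(), nt0 = T0.nrow(), ntip = tips.nrow();
  std::vector<V3> V;
  V.reserve(static_cast<size_t>(nv0) * 2);
  for (R_xlen_t i = 0; i < nv0; ++i) V.push_back({V0(i, 0), V0(i, 1), V0(i, 2)});
  std::vector<V3> tip(ntip);
  for (R_xlen_t i = 0; i < ntip; ++i) tip[i] = {tips(i, 0), tips(i, 1), tips(i, 2)};

  std::vector<std::array<uint32_t, 4>> T;
  std::vector<uint32_t> lev;
  T.reserve(static_cast<size_t>(nt0) * 4);
  lev.reserve(static_cast<size_t>(nt0) * 4);
  for (R_xlen_t i = 0; i < nt0; ++i) {
    T.push_back({static_cast<uint32_t>(T0(i, 0) - 1), static_cast<uint32_t>(T0(i, 1) - 1),
                 static_cast<uint32_t>(T0(i, 2) - 1), static_cast<uint32_t>(T0(i, 3) - 1)});
    lev.push_back(0u);
  }

  std::unordered_map<uint64_t, uint32_t> mid;
  mid.reserve(static_cast<size_t>(nt0) * 4);
  auto midpoint = [&](uint32_t a, uint32_t b) -> uint32_t {
    uint64_t k = ekey(a, b);
    auto it = mid.find(k);
    if (it != mid.end()) return it->second;
    V3 m{0.5 * (V[a].x + V[b].x), 0.5 * (V[a].y + V[b].y), 0.5 * (V[a].z + V[b].z)};
    V.push_back(m);
    uint32_t id = static_cast<uint32_t>(V.size() - 1);
    mid.emplace(k, id);
    return id;
  };

  static const int E[6][2] = {{0, 1}, {0, 2}, {0, 3}, {1, 2}, {1, 3}, {2, 3}};
  const double slack = 1.0 + 1e-9;

  bool changed = true;
  int pass = 0;
  while (changed) {
    if (++pass > max_pass)
      stop("mesh refinement did not terminate after %d passes (%d tets)",
           max_pass, (int)T.size());
    if (verbose && pass % 10 == 0)
      Rcpp::Rcout << "pass " << pass << ": " << T.size() << " tets, "
                  << V.size() << " vertices\n";
    changed = false;
    const size_t ncur = T.size();
    for (size_t t = 0; t < ncur; ++t) {
      std::array<uint32_t, 4> tet = T[t];
      double Lmax2 = -1.0;
      bool hang = false;
      for (int e = 0; e < 6; ++e) {
        uint32_t a = tet[E[e][0]], b = tet[E[e][1]];
        double L2 = dist2(V[a], V[b]);
        if (L2 > Lmax2) Lmax2 = L2;
        if (!hang && mid.count(ekey(a, b))) hang = true;
      }
      double L = std::sqrt(Lmax2);
      bool need = hang;
      if (!need && ntip > 0) {
        // lower bound on the tip-to-element distance: centroid distance
        // minus the circumradius bound max_v |v - c|; conservative (never
        // misses an intersecting element) but far tighter than a
        // vertex-distance bound for coarse elements
        V3 c{0.25 * (V[tet[0]].x + V[tet[1]].x + V[tet[2]].x + V[tet[3]].x),
             0.25 * (V[tet[0]].y + V[tet[1]].y + V[tet[2]].y + V[tet[3]].y),
             0.25 * (V[tet[0]].z + V[tet[1]].z + V[tet[2]].z + V[tet[3]].z)};
        double rmax2 = 0.0, dc2 = R_PosInf, dmin2 = R_PosInf;
        for (int v = 0; v < 4; ++v) {
          double r2 = dist2(V[tet[v]], c);
          if (r2 > rmax2) rmax2 = r2;
        }
        for (R_xlen_t k = 0; k < ntip; ++k) {
          double d2 = dist2(c, tip[k]);
          if (d2 < dc2) dc2 = d2;
          for (int v = 0; v < 4; ++v) {
            double d2v = dist2(V[tet[v]], tip[k]);
            if (d2v < dmin2) dmin2 = d2v;
          }
        }
        double dlow = std::max(0.0, std::sqrt(dc2) - std::sqrt(rmax2));
        double lim = (dlow <= soi_radius)
                         ? tip_edge
                         : tip_edge + grade_slope * (std::sqrt(dmin2) - soi_radius);
        if (L > lim * slack) need = true;
      }
      if (!need) continue;
      // Maubach bisection at the level-determined refinement edge
      const uint32_t l = lev[t];
      const int k = 3 - static_cast<int>(l % 3u);
      uint32_t m = midpoint(tet[0], tet[k]);
      std::array<uint32_t, 4> c1, c2;
      for (int j = 0; j < 4; ++j) c1[j] = tet[j];
      c1[k] = m;
      for (int j = 0; j < k; ++j) c2[j] = tet[j + 1];
      c2[k] = m;
      for (int j = k + 1; j < 4; ++j) c2[j] = tet[j];
      T[t] = c1;
      lev[t] = l + 1;
      T.push_back(c2);
      lev.push_back(l + 1);
      changed = true;
    }
    Rcpp::checkUserInterrupt();
  }

  NumericMatrix Vout(static_cast<R_xlen_t>(V.size()), 3);
  for (size_t i = 0; i < V.size(); ++i) {
    Vout(i, 0) = V[i].x; Vout(i, 1) = V[i].y; Vout(i, 2) = V[i].z;
  }
  IntegerMatrix Tout(static_cast<R_xlen_t>(T.size()), 4);
  for (size_t i = 0; i < T.size(); ++i)
    for (int j = 0; j < 4; ++j) Tout(i, j) = static_cast<int>(T[i][j]) + 1;
  return List::create(_["nodes"] = Vout, _["tets"] = Tout, _["passes"] = pass);
}

// Insert midside nodes on every unique edge: 4-node tets -> 10-node tets.
// Node order per element: 4 vertices then edges (1,2),(1,3),(1,4),(2,3),(2,4),(3,4).
// [[Rcpp::export(name = ".tet10_build_cpp")]]
List tet10_build_cpp(NumericMatrix V, IntegerMatrix T) {
  const R_xlen_t nv = V.nrow(), nt = T.nrow();
  std::unordered_map<uint64_t, uint32_t> mid;
  mid.reserve(static_cast<size_t>(nt) * 4);
  std::vector<V3> extra;
  extra.reserve(static_cast<size_t>(nt) * 2);
  static const int E[6][2] = {{0, 1}, {0, 2}, {0, 3}, {1, 2}, {1, 3}, {2, 3}};
  IntegerMatrix T10(nt, 10);
  for (R_xlen_t t = 0; t < nt; ++t) {
    uint32_t vid[4];
    for (int j = 0; j < 4; ++j) {
      vid[j] = static_cast<uint32_t>(T(t, j) - 1);
      T10(t, j) = T(t, j);
    }
    for (int e = 0; e < 6; ++e) {
      uint32_t a = vid[E[e][0]], b = vid[E[e][1]];
      uint64_t k = ekey(a, b);
      auto it = mid.find(k);
      uint32_t id;
      if (it != mid.end()) id = it->second;
      else {
        extra.push_back({0.5 * (V(a, 0) + V(b, 0)), 0.5 * (V(a, 1) + V(b, 1)),
                         0.5 * (V(a, 2) + V(b, 2))});
        id = static_cast<uint32_t>(nv + extra.size() - 1);
        mid.emplace(k, id);
      }
      T10(t, 4 + e) = static_cast<int>(id) + 1;
    }
  }
  NumericMatrix nodes(nv + static_cast<R_xlen_t>(extra.size()), 3);
  for (R_xlen_t i = 0; i < nv; ++i)
    for (int j = 0; j < 3; ++j) nodes(i, j) = V(i, j);
  for (size_t i = 0; i < extra.size(); ++i) {
    nodes(nv + i, 0) = extra[i].x;
    nodes(nv + i, 1) = extra[i].y;
    nodes(nv + i, 2) = extra[i].z;
  }
  // parent vertices of each midside node (rows aligned with node ids
  // nv+1 ... nv+nmid); used for the quadratic->linear hierarchy transfer
  IntegerMatrix par(static_cast<R_xlen_t>(extra.size()), 2);
  for (const auto &kv : mid) {
    R_xlen_t row = static_cast<R_xlen_t>(kv.second) - nv;
    par(row, 0) = static_cast<int>(kv.first >> 32) + 1;
    par(row, 1) = static_cast<int>(kv.first & 0xffffffffu) + 1;
  }
  return List::create(_["nodes"] = nodes, _["tets10"] = T10, _["n_vertex"] = nv,
                      _["midside_parents"] = par);
}

// Geometric nested-dissection ordering of mesh nodes: elements are split
// recursively by centroid along the widest coordinate axis; nodes shared
// by both halves form the separator and are ordered last.  Greatly
// reduces sparse Cholesky fill relative to minimum-degree orderings on
// 3D mesh graphs.
namespace {
void nd_recurse(const std::vector<std::array<double,3>> &cent,
                const NumericMatrix &X, const IntegerMatrix &T,
                std::vector<int> &elems, std::vector<char> &assigned,
                std::vector<int> &order) {
  // collect unassigned nodes of this element set
  std::vector<int> nodes;
  for (int e : elems)
    for (int j = 0; j < T.ncol(); ++j) {
      int v = T(e, j) - 1;
      if (!assigned[v]) { nodes.push_back(v); }
    }
  std::sort(nodes.begin(), nodes.end());
  nodes.erase(std::unique(nodes.begin(), nodes.end()), nodes.end());
  if (nodes.size() <= 64 || elems.size() <= 16) {
    for (int v : nodes) { order.push_back(v); assigned[v] = 1; }
    return;
  }
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf},
         hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int e : elems)
    for (int a = 0; a < 3; ++a) {
      lo[a] = std::min(lo[a], cent[e][a]);
      hi[a] = std::max(hi[a], cent[e][a]);
    }
  // Choose the cut plane that crosses the fewest elements while keeping
  // the split reasonably balanced.  On graded meshes a fixed midpoint or
  // count-median plane tends to slice through the refined zone and blow
  // up the separator.
  int best_ax = -1;
  double best_off = 0, best_score = R_PosInf;
  const size_t ne = elems.size();
  for (int a = 0; a < 3; ++a) {
    if (hi[a] - lo[a] <= 0) continue;
    for (int q = 2; q <= 8; ++q) {
      double off = lo[a] + (hi[a] - lo[a]) * q / 10.0;
      size_t na = 0, cross = 0;
      for (int e : elems) {
        double emin = R_PosInf, emax = R_NegInf;
        for (int j = 0; j < T.ncol(); ++j) {
          double c = X(T(e, j) - 1, a);
          emin = std::min(emin, c);
          emax = std::max(emax, c);
        }
        if (cent[e][a] < off) ++na;
        if (emin < off && emax > off) ++cross;
      }
      double bal = static_cast<double>(na) / ne;
      if (bal < 0.15 || bal > 0.85) continue;
      double score = cross + 0.1 * ne * std::fabs(bal - 0.5);
      if (score < best_score) { best_score = score; best_ax = a; best_off = off; }
    }
  }
  if (best_ax < 0) { // no admissible plane: emit everything
    for (int v : nodes) { order.push_back(v); assigned[v] = 1; }
    return;
  }
  const int ax = best_ax;
  const double med = best_off;
  std::vector<int> ea, eb;
  for (int e : elems)
    (cent[e][ax] < med ? ea : eb).push_back(e);
  if (ea.empty() || eb.empty()) {
    for (int v : nodes) { order.push_back(v); assigned[v] = 1; }
    return;
  }
  // separator: nodes appearing in both halves
  std::vector<char> inA(X.nrow(), 0);
  for (int e : ea)
    for (int j = 0; j < T.ncol(); ++j) inA[T(e, j) - 1] = 1;
  std::vector<int> sep;
  std::vector<char> insep(X.nrow(), 0);
  for (int e : eb)
    for (int j = 0; j < T.ncol(); ++j) {
      int v = T(e, j) - 1;
      if (inA[v] && !assigned[v] && !insep[v]) { sep.push_back(v); insep[v] = 1; }
    }
  for (int v : sep) assigned[v] = 1; // reserve; emitted after the halves
  nd_recurse(cent, X, T, ea, assigned, order);
  nd_recurse(cent, X, T, eb, assigned, order);
  for (int v : sep) order.push_back(v);
}
} // namespace

// [[Rcpp::export(name = ".nd_order_cpp")]]
IntegerVector nd_order_cpp(NumericMatrix X, IntegerMatrix T) {
  const R_xlen_t ne = T.nrow();
  std::vector<std::array<double,3>> cent(ne);
  for (R_xlen_t e = 0; e < ne; ++e) {
    double cx = 0, cy = 0, cz = 0;
    for (int j = 0; j < 4; ++j) { // vertex centroid is enough
      int v = T(e, j) - 1;
      cx += X(v, 0); cy += X(v, 1); cz += X(v, 2);
    }
    cent[e] = {cx / 4, cy / 4, cz / 4};
  }
  std::vector<int> elems(ne);
  for (R_xlen_t e = 0; e < ne; ++e) elems[e] = e;
  std::vector<char> assigned(X.nrow(), 0);
  std::vector<int> order;
  order.reserve(X.nrow());
  nd_recurse(cent, X, T, elems, assigned, order);
  for (int v = 0; v < X.nrow(); ++v)
    if (!assigned[v]) order.push_back(v); // nodes not in any element
  IntegerVector out(order.size());
  for (size_t i = 0; i < order.size(); ++i) out[i] = order[i] + 1;
  return out;
}
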