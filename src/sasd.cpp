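// Voxel-grid labelling and solvent shortest-path search.
//
// Labels: 0 = solvent, 1 = protein, 2 = buried cavity.
// Voxel (i,j,k) with 0-based indices maps to linear index
// i + nx*(j + ny*k); voxel centers are origin + (i,j,k)*spacing.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// [[Rcpp::export]]
IntegerVector cpp_label_grid(NumericMatrix coords, NumericVector radii,
                             NumericVector origin, IntegerVector dim,
                             double spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  IntegerVector labels(nvox, 2);  // start as "not protein, not solvent"

  // mark protein voxels: center within radii[a] of atom a
  for (int a = 0; a < coords.nrow(); ++a) {
    const double ax = coords(a, 0), ay = coords(a, 1), az = coords(a, 2);
    const double r = radii[a], r2 = r * r;
    int i0 = (int)std::ceil((ax - r - origin[0]) / spacing);
    int i1 = (int)std::floor((ax + r - origin[0]) / spacing);
    int j0 = (int)std::ceil((ay - r - origin[1]) / spacing);
    int j1 = (int)std::floor((ay + r - origin[1]) / spacing);
    int k0 = (int)std::ceil((az - r - origin[2]) / spacing);
    int k1 = (int)std::floor((az + r - origin[2]) / spacing);
    if (i0 < 0) i0 = 0; if (i1 >= nx) i1 = nx - 1;
    if (j0 < 0) j0 = 0; if (j1 >= ny) j1 = ny - 1;
    if (k0 < 0) k0 = 0; if (k1 >= nz) k1 = nz - 1;
    for (int k = k0; k <= k1; ++k) {
      const double dz = origin[2] + k * spacing - az;
      for (int j = j0; j <= j1; ++j) {
        const double dy = origin[1] + j * spacing - ay;
        const double dyz = dy * dy + dz * dz;
        if (dyz > r2) continue;
        for (int i = i0; i <= i1; ++i) {
          const double dx = origin[0] + i * spacing - ax;
          if (dx * dx + dyz <= r2)
            labels[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = 1;
        }
      }
    }
  }

  // flood fill solvent from the grid boundary (6-connectivity so solvent
  // cannot leak diagonally through a one-voxel protein wall)
  std::queue<R_xlen_t> q;
  auto idx = [&](int i, int j, int k) {
    return (R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
  };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (i > 0 && i < nx - 1 && j > 0 && j < ny - 1 &&
            k > 0 && k < nz - 1) continue;
        R_xlen_t v = idx(i, j, k);
        if (labels[v] == 2) { labels[v] = 0; q.push(v); }
      }
  const int di[6] = {1, -1, 0, 0, 0, 0};
  const int dj[6] = {0, 0, 1, -1, 0, 0};
  const int dk[6] = {0, 0, 0, 0, 1, -1};
  while (!q.empty()) {
    R_xlen_t v = q.front(); q.pop();
    int k = (int)(v / ((R_xlen_t)nx * ny));
    int rem = (int)(v % ((R_xlen_t)nx * ny));
    int j = rem / nx, i = rem % nx;
    for (int d = 0; d < 6; ++d) {
      int ii = i + di[d], jj = j + dj[d], kk = k + dk[d];
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
        continue;
      R_xlen_t w = idx(ii, jj, kk);
      if (labels[w] == 2) { labels[w] = 0; q.push(w); }
    }
  }
  return labels;
}

// Dijkstra over solvent voxels, 26-connectivity, metric edge weights.
// sources: 0-based voxel indices; source_init: starting distances
// (anchor-to-entry offsets). Distances above `cap` are not expanded.
// When `targets` is non-empty the search stops once every target voxel is
// settled (or proven unreachable within the cap).
// Returns per-voxel distance (Inf where unreached or non-solvent).
// [[Rcpp::export]]
NumericVector cpp_dijkstra(IntegerVector labels, IntegerVector dim,
                           double spacing, IntegerVector sources,
                           NumericVector source_init, double cap,
                           IntegerVector targets =
                             IntegerVector::create()) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const double inf = std::numeric_limits<double>::infinity();
  std::vector<double> dist(nvox, inf);

  // 26 neighbor offsets with Euclidean step lengths
  int di[26], dj[26], dk[26];
  double w[26];
  int m = 0;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (!a && !b && !c) continue;
        di[m] = a; dj[m] = b; dk[m] = c;
        w[m] = spacing * std::sqrt((double)(a * a + b * b + c * c));
        ++m;
      }

  std::vector<char> is_target(nvox, 0);
  R_xlen_t n_unsettled = 0;
  for (int t = 0; t < targets.size(); ++t) {
    R_xlen_t v = targets[t];
    if (v >= 0 && v < nvox && !is_target[v]) {
      is_target[v] = 1;
      ++n_unsettled;
    }
  }
  typedef std::pair<double, R_xlen_t> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  for (int s = 0; s < sources.size(); ++s) {
    R_xlen_t v = sources[s];
    if (v < 0 || v >= nvox || labels[v] != 0) continue;
    if (source_init[s] < dist[v]) {
      dist[v] = source_init[s];
      pq.push(Node(dist[v], v));
    }
  }
  while (!pq.empty()) {
    Node top = pq.top(); pq.pop();
    double d = top.first;
    R_xlen_t v = top.second;
    if (d > dist[v]) continue;
    if (d > cap) continue;
    if (is_target[v]) {
      is_target[v] = 0;
      if (--n_unsettled == 0 && targets.size() > 0) break;
    }
    int k = (int)(v / ((R_xlen_t)nx * ny));
    int rem = (int)(v % ((R_xlen_t)nx * ny));
    int j = rem / nx, i = rem % nx;
    for (int t = 0; t < 26; ++t) {
      int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
        continue;
      R_xlen_t u = (R_xlen_t)ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
      if (labels[u] != 0) continue;
      double nd = d + w[t];
      if (nd < dist[u] && nd <= cap) {
        dist[u] = nd;
        pq.push(Node(nd, u));
      }
    }
  }
  return NumericVector(dist.begin(), dist.end());
}

// count pairs between two coordinate sets closer than per-pair cutoffs
// cutoff = frac * (ra[i] + rb[j]); with frac <= 0, `fixed` is used instead.
// Returns: total pair count, plus which atoms of each set are involved.
// [[Rcpp::export]]
List cpp_close_pairs(NumericMatrix a, NumericMatrix b,
                     NumericVector ra, NumericVector rb,
                     double frac, double fixed) {
  int na = a.nrow(), nb = b.nrow();
  LogicalVector hit_a(na, false), hit_b(nb, false);
  double count = 0;
  for (int i = 0; i < na; ++i) {
    for (int j = 0; j < nb; ++j) {
      double cut = frac > 0 ? frac * (ra[i] + rb[j]) : fixed;
      double dx = a(i, 0) - b(j, 0);
      double dy = a(i, 1) - b(j, 1);
      double dz = a(i, 2) - b(j, 2);
      if (dx * dx + dy * dy + dz * dz < cut * cut) {
        count += 1;
        hit_a[i] = true;
        hit_b[j] = true;
      }
    }
  }
  return List::create(_["count"] = count, _["hit_a"] = hit_a,
                      _["hit_b"] = hit_b);
}
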