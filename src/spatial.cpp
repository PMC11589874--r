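// Spatial search kernels: uniform grid-hash index with exact radius and
// k-nearest-neighbour queries, DBSCAN, per-point PCA features, and the
// incremental fuzzy-kNN layer sweep used by the fine segmentation.
//
// All queries are exact; the grid is an acceleration structure only.

#include <RcppArmadillo.h>
#include <unordered_map>
#include <queue>
#include <cmath>
#include <limits>

// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// 21 bits per axis, shifted to stay positive; fine for |cell index| < 2^20.
inline long long cellKey(long long ix, long long iy, long long iz) {
  const long long B = 1LL << 20;
  return ((ix + B) << 42) | ((iy + B) << 21) | (iz + B);
}

struct GridIndex {
  double h;
  const double* x;
  const double* y;
  const double* z;        // null for 2-D data
  int n;
  long long clo[3], chi[3];  // occupied cell bounds
  std::unordered_map<long long, std::vector<int>> cells;

  void initBounds() {
    for (int a = 0; a < 3; ++a) {
      clo[a] = std::numeric_limits<long long>::max();
      chi[a] = std::numeric_limits<long long>::min();
    }
  }

  GridIndex(const NumericMatrix& pts, double cell)
      : h(cell), x(nullptr), y(nullptr), z(nullptr), n(pts.nrow()) {
    initBounds();
    x = &pts(0, 0);
    y = &pts(0, 1);
    if (pts.ncol() > 2) z = &pts(0, 2);
    cells.reserve(static_cast<size_t>(n) * 2 + 8);
    for (int i = 0; i < n; ++i) insert(i);
  }

  GridIndex(double cell, int capacity)
      : h(cell), x(nullptr), y(nullptr), z(nullptr), n(0) {
    initBounds();
    cells.reserve(static_cast<size_t>(capacity) * 2 + 8);
  }

  inline double zi(int i) const { return z ? z[i] : 0.0; }

  inline long long keyOf(double px, double py, double pz) const {
    return cellKey((long long)std::floor(px / h), (long long)std::floor(py / h),
                   (long long)std::floor(pz / h));
  }

  void insert(int i) {
    long long ci[3] = {(long long)std::floor(x[i] / h),
                       (long long)std::floor(y[i] / h),
                       (long long)std::floor(zi(i) / h)};
    for (int a = 0; a < 3; ++a) {
      clo[a] = std::min(clo[a], ci[a]);
      chi[a] = std::max(chi[a], ci[a]);
    }
    cells[cellKey(ci[0], ci[1], ci[2])].push_back(i);
  }

  inline double dist2(int i, double qx, double qy, double qz) const {
    double dx = x[i] - qx, dy = y[i] - qy, dz = zi(i) - qz;
    return dx * dx + dy * dy + dz * dz;
  }

  // All indices with distance <= r from (qx,qy,qz).
  void radius(double qx, double qy, double qz, double r,
              std::vector<int>& out) const {
    out.clear();
    double r2 = r * r;
    int span = (int)std::ceil(r / h);
    long long cx = (long long)std::floor(qx / h);
    long long cy = (long long)std::floor(qy / h);
    long long cz = (long long)std::floor(qz / h);
    long long zlo = z ? cz - span : 0, zhi = z ? cz + span : 0;
    for (long long ix = cx - span; ix <= cx + span; ++ix)
      for (long long iy = cy - span; iy <= cy + span; ++iy)
        for (long long iz = zlo; iz <= zhi; ++iz) {
          auto it = cells.find(cellKey(ix, iy, z ? iz : 0));
          if (it == cells.end()) continue;
          for (int i : it->second)
            if (dist2(i, qx, qy, qz) <= r2) out.push_back(i);
        }
  }

  // Exact k nearest neighbours by expanding Chebyshev shells. Cells in shell
  // R are at least (R-1)*h away from the query, so the search can stop once
  // the current k-th distance is below that bound.
  void knn(double qx, double qy, double qz, int k, std::vector<int>& idx,
           std::vector<double>& dst) const {
    idx.clear();
    dst.clear();
    if (n == 0 || cells.empty()) return;
    typedef std::pair<double, int> DI;  // (dist2, index), max-heap
    std::priority_queue<DI> heap;
    long long cx = (long long)std::floor(qx / h);
    long long cy = (long long)std::floor(qy / h);
    long long cz = z ? (long long)std::floor(qz / h) : 0;
    // Once the shell radius covers the whole occupied grid relative to the
    // query cell, every point has been seen.
    long long maxShell = 0;
    long long qc[3] = {cx, cy, cz};
    for (int a = 0; a < 3; ++a) {
      if (!z && a == 2) continue;
      maxShell = std::max(maxShell, std::llabs(qc[a] - clo[a]));
      maxShell = std::max(maxShell, std::llabs(qc[a] - chi[a]));
    }
    for (int R = 0;; ++R) {
      bool any = false;
      long long zlo = z ? cz - R : 0, zhi = z ? cz + R : 0;
      for (long long ix = cx - R; ix <= cx + R; ++ix)
        for (long long iy = cy - R; iy <= cy + R; ++iy)
          for (long long iz = zlo; iz <= zhi; ++iz) {
            long long chb = std::max(std::llabs(ix - cx), std::llabs(iy - cy));
            if (z) chb = std::max(chb, std::llabs(iz - cz));
            if (chb != R) continue;  // shell only
            auto it = cells.find(cellKey(ix, iy, iz));
            if (it == cells.end()) continue;
            any = true;
            for (int i : it->second) {
              double d2 = dist2(i, qx, qy, qz);
              if ((int)heap.size() < k)
                heap.push(DI(d2, i));
              else if (d2 < heap.top().first) {
                heap.pop();
                heap.push(DI(d2, i));
              }
            }
          }
      (void)any;
      if ((int)heap.size() >= k) {
        double bound = (double)R * h;  // next shells are >= R*h away
        if (heap.top().first <= bound * bound) break;
      }
      if ((long long)R > maxShell) break;  // all cells visited
    }
    size_t m = heap.size();
    idx.resize(m);
    dst.resize(m);
    for (size_t j = m; j-- > 0;) {
      idx[j] = heap.top().second;
      dst[j] = std::sqrt(heap.top().first);
      heap.pop();
    }
  }
};

double heuristicCell(const NumericMatrix& pts) {
  int n = pts.nrow(), d = pts.ncol();
  if (n == 0) return 1.0;
  double vol = 1.0;
  int used = 0;
  for (int j = 0; j < d; ++j) {
    double lo = R_PosInf, hi = R_NegInf;
    for (int i = 0; i < n; ++i) {
      lo = std::min(lo, pts(i, j));
      hi = std::max(hi, pts(i, j));
    }
    double r = hi - lo;
    if (r > 0) {
      vol *= r;
      ++used;
    }
  }
  if (used == 0) return 1.0;
  double cell = 2.0 * std::pow(vol / std::max(n, 1), 1.0 / used);
  return std::max(cell, 1e-9);
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = "cpp_knn")]]
List cpp_knn(NumericMatrix ref, NumericMatrix query, int k) {
  if (ref.nrow() == 0) stop("reference point set is empty");
  k = std::min(k, (int)ref.nrow());
  GridIndex g(ref, heuristicCell(ref));
  int m = query.nrow();
  IntegerMatrix idx(m, k);
  NumericMatrix dst(m, k);
  std::vector<int> ii;
  std::vector<double> dd;
  bool has3 = query.ncol() > 2;
  for (int q = 0; q < m; ++q) {
    g.knn(query(q, 0), query(q, 1), has3 ? query(q, 2) : 0.0, k, ii, dd);
    for (int j = 0; j < k; ++j) {
      idx(q, j) = ii[j] + 1;
      dst(q, j) = dd[j];
    }
  }
  return List::create(_["index"] = idx, _["distance"] = dst);
}

//' @noRd
// [[Rcpp::export(name = "cpp_radius_count")]]
IntegerVector cpp_radius_count(NumericMatrix pts, double radius) {
  GridIndex g(pts, radius > 0 ? radius : 1.0);
  int n = pts.nrow();
  IntegerVector out(n);
  std::vector<int> nb;
  bool has3 = pts.ncol() > 2;
  for (int i = 0; i < n; ++i) {
    g.radius(pts(i, 0), pts(i, 1), has3 ? pts(i, 2) : 0.0, radius, nb);
    out[i] = (int)nb.size();
  }
  return out;
}

// Per-point neighbourhood PCA. Returns n x 8: neighbour count, linearity
// (l1-l2)/l1, dominant eigenvector (3), smallest eigenvector (3).
//' @noRd
// [[Rcpp::export(name = "cpp_local_pca")]]
NumericMatrix cpp_local_pca(NumericMatrix pts, double radius, int min_pts) {
  int n = pts.nrow();
  NumericMatrix out(n, 8);
  GridIndex g(pts, radius);
  std::vector<int> nb;
  arma::mat33 C;
  arma::vec3 mu;
  for (int i = 0; i < n; ++i) {
    g.radius(pts(i, 0), pts(i, 1), pts(i, 2), radius, nb);
    int m = (int)nb.size();
    out(i, 0) = m;
    if (m < std::max(min_pts, 3)) {
      out(i, 1) = NA_REAL;
      continue;
    }
    mu.zeros();
    for (int j : nb) {
      mu[0] += pts(j, 0);
      mu[1] += pts(j, 1);
      mu[2] += pts(j, 2);
    }
    mu /= m;
    C.zeros();
    for (int j : nb) {
      double dx = pts(j, 0) - mu[0], dy = pts(j, 1) - mu[1],
             dz = pts(j, 2) - mu[2];
      C(0, 0) += dx * dx;
      C(0, 1) += dx * dy;
      C(0, 2) += dx * dz;
      C(1, 1) += dy * dy;
      C(1, 2) += dy * dz;
      C(2, 2) += dz * dz;
    }
    C(1, 0) = C(0, 1);
    C(2, 0) = C(0, 2);
    C(2, 1) = C(1, 2);
    C /= m;
    arma::vec eval;
    arma::mat evec;
    if (!arma::eig_sym(eval, evec, arma::mat(C))) {
      out(i, 1) = NA_REAL;
      continue;
    }
    // eig_sym: ascending eigenvalues
    double l1 = eval[2], l2 = eval[1];
    out(i, 1) = l1 > 0 ? (l1 - l2) / l1 : 0.0;
    for (int a = 0; a < 3; ++a) {
      out(i, 2 + a) = evec(a, 2);  // dominant
      out(i, 5 + a) = evec(a, 0);  // smallest (plane normal)
    }
  }
  return out;
}

// Deterministic DBSCAN: BFS expansion from the lowest-index unvisited core
// point; border points join the first cluster that reaches them. Labels:
// 0 = noise, clusters numbered 1..k in order of creation.
//' @noRd
// [[Rcpp::export(name = "cpp_dbscan")]]
IntegerVector cpp_dbscan(NumericMatrix pts, double eps, int min_pts) {
  int n = pts.nrow();
  IntegerVector labels(n, 0);
  if (n == 0) return labels;
  GridIndex g(pts, eps > 0 ? eps : 1.0);
  bool has3 = pts.ncol() > 2;
  std::vector<int> nb;
  std::vector<char> core(n, 0);
  for (int i = 0; i < n; ++i) {
    g.radius(pts(i, 0), pts(i, 1), has3 ? pts(i, 2) : 0.0, eps, nb);
    core[i] = (int)nb.size() >= min_pts;  // neighbourhood includes self
  }
  std::vector<char> visited(n, 0);
  int cl = 0;
  std::vector<int> stack;
  for (int i = 0; i < n; ++i) {
    if (visited[i] || !core[i]) continue;
    ++cl;
    stack.clear();
    stack.push_back(i);
    visited[i] = 1;
    labels[i] = cl;
    while (!stack.empty()) {
      int p = stack.back();
      stack.pop_back();
      if (!core[p]) continue;  // border: claimed but not expanded
      g.radius(pts(p, 0), pts(p, 1), has3 ? pts(p, 2) : 0.0, eps, nb);
      std::sort(nb.begin(), nb.end());
      for (int q : nb) {
        if (visited[q]) continue;
        visited[q] = 1;
        labels[q] = cl;
        stack.push_back(q);
      }
    }
  }
  return labels;
}

// Iterative fuzzy-kNN sweep. labels0: 0 = unlabeled, >0 = seed label.
// layer: integer layer id per point; layers processed in ascending order if
// bottom_up, else descending; unlabeled points within a layer in ascending
// index order. A point whose nearest labeled neighbour is farther than
// max_dist stays 0 (unassigned); otherwise it takes the argmax fuzzy
// membership over its k nearest labeled points (weights d^(-2/(m-1)),
// ties to the smallest label) and immediately joins the labeled set.
//' @noRd
// [[Rcpp::export(name = "cpp_fknn_sweep")]]
IntegerVector cpp_fknn_sweep(NumericMatrix pts, IntegerVector labels0,
                             IntegerVector layer, bool bottom_up, int k,
                             double m, double max_dist) {
  int n = pts.nrow();
  IntegerVector labels = clone(labels0);
  if (n == 0) return labels;

  GridIndex g(max_dist > 0 ? max_dist : 1.0, n);
  g.x = &pts(0, 0);
  g.y = &pts(0, 1);
  g.z = &pts(0, 2);
  g.n = n;
  int nSeed = 0;
  for (int i = 0; i < n; ++i)
    if (labels[i] > 0) {
      g.insert(i);
      ++nSeed;
    }
  if (nSeed == 0) stop("no seed labels");

  // order layers
  std::vector<int> uniq(layer.begin(), layer.end());
  std::sort(uniq.begin(), uniq.end());
  uniq.erase(std::unique(uniq.begin(), uniq.end()), uniq.end());
  if (!bottom_up) std::reverse(uniq.begin(), uniq.end());
  std::unordered_map<int, std::vector<int>> byLayer;
  for (int i = 0; i < n; ++i) byLayer[layer[i]].push_back(i);

  std::vector<int> ii;
  std::vector<double> dd;
  std::unordered_map<int, double> vote;
  for (int L : uniq) {
    for (int i : byLayer[L]) {  // ascending index (insertion order)
      if (labels[i] > 0) continue;
      int kk = std::min(k, nSeed);
      g.knn(pts(i, 0), pts(i, 1), pts(i, 2), kk, ii, dd);
      if (ii.empty() || dd[0] > max_dist) {
        labels[i] = 0;
        continue;
      }
      int best = -1;
      if (dd[0] <= 0.0) {
        best = labels[ii[0]];  // exact coincidence: full membership
      } else {
        vote.clear();
        for (size_t j = 0; j < ii.size(); ++j) {
          double w = std::pow(dd[j], -2.0 / (m - 1.0));
          vote[labels[ii[j]]] += w;
        }
        double hi = -1.0;
        for (auto& kv : vote)
          if (kv.second > hi + 1e-15 ||
              (std::fabs(kv.second - hi) <= 1e-15 && kv.first < best)) {
            hi = kv.second;
            best = kv.first;
          }
      }
      labels[i] = best;
      g.insert(i);
      ++nSeed;
    }
  }
  return labels;
}
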