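// Point-set primitives: iterative farthest point sampling, exact nearest
// neighbours (brute force and kd-tree, guaranteed identical results), and
// exact earth mover's distance via shortest augmenting paths.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <limits>
#include <vector>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// ---------------------------------------------------------------------------
// Iterative farthest point sampling (greedy max-min). Ties in the argmax are
// broken toward the lowest index (strict > comparison while scanning up).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerVector fps_cpp(NumericMatrix pts, int k, int start) {
  const int n = pts.nrow();
  if (k < 1 || k > n) stop("k must be in [1, n]");
  if (start < 1 || start > n) stop("start index out of range");
  std::vector<double> x(n), y(n), z(n), d2(n, INF);
  for (int i = 0; i < n; ++i) { x[i] = pts(i, 0); y[i] = pts(i, 1); z[i] = pts(i, 2); }
  IntegerVector out(k);
  int cur = start - 1;
  out[0] = cur + 1;
  for (int j = 1; j < k; ++j) {
    const double cx = x[cur], cy = y[cur], cz = z[cur];
    int best = -1;
    double bestd = -1.0;
    for (int i = 0; i < n; ++i) {
      const double dx = x[i] - cx, dy = y[i] - cy, dz = z[i] - cz;
      const double dd = dx * dx + dy * dy + dz * dz;
      if (dd < d2[i]) d2[i] = dd;
      if (d2[i] > bestd) { bestd = d2[i]; best = i; }
    }
    cur = best;
    out[j] = cur + 1;
  }
  return out;
}

// ---------------------------------------------------------------------------
// kd-tree for exact 3D nearest-neighbour queries. Equidistant candidates are
// resolved toward the lowest point index, matching the brute-force scan, so
// both back ends return bit-identical answers.
// ---------------------------------------------------------------------------
struct KDTree {
  struct Node { int lo, hi, axis, left, right; double split; };
  std::vector<double> px, py, pz;
  std::vector<int> perm;   // permutation of point indices, leaves hold ranges
  std::vector<Node> nodes;
  int leaf_size;

  double coord(int idx, int ax) const {
    return ax == 0 ? px[idx] : (ax == 1 ? py[idx] : pz[idx]);
  }

  int build(int lo, int hi) {
    Node nd;
    nd.lo = lo; nd.hi = hi; nd.left = nd.right = -1; nd.axis = -1; nd.split = 0.0;
    int id = (int)nodes.size();
    nodes.push_back(nd);
    if (hi - lo <= leaf_size) return id;
    double mn[3] = { INF, INF, INF }, mx[3] = { -INF, -INF, -INF };
    for (int i = lo; i < hi; ++i)
      for (int a = 0; a < 3; ++a) {
        double c = coord(perm[i], a);
        if (c < mn[a]) mn[a] = c;
        if (c > mx[a]) mx[a] = c;
      }
    int ax = 0;
    double wid = mx[0] - mn[0];
    for (int a = 1; a < 3; ++a)
      if (mx[a] - mn[a] > wid) { wid = mx[a] - mn[a]; ax = a; }
    if (wid <= 0.0) return id;  // all points identical: stay a leaf
    int mid = (lo + hi) / 2;
    std::nth_element(perm.begin() + lo, perm.begin() + mid, perm.begin() + hi,
                     [&](int a, int b) { return coord(a, ax) < coord(b, ax); });
    nodes[id].axis = ax;
    nodes[id].split = coord(perm[mid], ax);
    int l = build(lo, mid);
    int r = build(mid, hi);
    nodes[id].left = l;
    nodes[id].right = r;
    return id;
  }

  void init(const NumericMatrix& pts, int leaf = 16) {
    int n = pts.nrow();
    leaf_size = leaf;
    px.resize(n); py.resize(n); pz.resize(n); perm.resize(n);
    for (int i = 0; i < n; ++i) {
      px[i] = pts(i, 0); py[i] = pts(i, 1); pz[i] = pts(i, 2); perm[i] = i;
    }
    nodes.reserve(2 * n / leaf + 4);
    build(0, n);
  }

  void nn1(int node, double qx, double qy, double qz,
           double& bestd2, int& bestidx) const {
    const Node& nd = nodes[node];
    if (nd.axis < 0) {  // leaf
      for (int i = nd.lo; i < nd.hi; ++i) {
        int p = perm[i];
        double dx = px[p] - qx, dy = py[p] - qy, dz = pz[p] - qz;
        double dd = dx * dx + dy * dy + dz * dz;
        if (dd < bestd2 || (dd == bestd2 && p < bestidx)) { bestd2 = dd; bestidx = p; }
      }
      return;
    }
    double q = nd.axis == 0 ? qx : (nd.axis == 1 ? qy : qz);
    double diff = q - nd.split;
    int near = diff <= 0 ? nd.left : nd.right;
    int far  = diff <= 0 ? nd.right : nd.left;
    nn1(near, qx, qy, qz, bestd2, bestidx);
    if (diff * diff <= bestd2)  // <= keeps equidistant candidates reachable
      nn1(far, qx, qy, qz, bestd2, bestidx);
  }
};

// [[Rcpp::export]]
List nn_brute_cpp(NumericMatrix query, NumericMatrix ref) {
  const int nq = query.nrow(), nr = ref.nrow();
  IntegerVector idx(nq);
  NumericVector d2(nq);
  std::vector<double> rx(nr), ry(nr), rz(nr);
  for (int j = 0; j < nr; ++j) { rx[j] = ref(j, 0); ry[j] = ref(j, 1); rz[j] = ref(j, 2); }
  for (int i = 0; i < nq; ++i) {
    const double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    double best = INF;
    int bi = -1;
    for (int j = 0; j < nr; ++j) {
      const double dx = rx[j] - qx, dy = ry[j] - qy, dz = rz[j] - qz;
      const double dd = dx * dx + dy * dy + dz * dz;
      if (dd < best) { best = dd; bi = j; }
    }
    idx[i] = bi + 1;
    d2[i] = best;
  }
  return List::create(_["idx"] = idx, _["d2"] = d2);
}

// [[Rcpp::export]]
List nn_kdtree_cpp(NumericMatrix query, NumericMatrix ref) {
  KDTree tree;
  tree.init(ref);
  const int nq = query.nrow();
  IntegerVector idx(nq);
  NumericVector d2(nq);
  for (int i = 0; i < nq; ++i) {
    double bd = INF;
    int bi = ref.nrow();  // sentinel larger than any index
    tree.nn1(0, query(i, 0), query(i, 1), query(i, 2), bd, bi);
    idx[i] = bi + 1;
    d2[i] = bd;
  }
  return List::create(_["idx"] = idx, _["d2"] = d2);
}

// ---------------------------------------------------------------------------
// Self k-nearest-neighbours (excluding the query point itself). Brute force:
// used for outlier statistics, normal estimation and region growing on
// preprocessing-scale clouds.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List knn_self_cpp(NumericMatrix pts, int k) {
  const int n = pts.nrow();
  if (k < 1 || k >= n) stop("k must be in [1, n-1]");
  IntegerMatrix idx(n, k);
  NumericMatrix dist(n, k);
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) { x[i] = pts(i, 0); y[i] = pts(i, 1); z[i] = pts(i, 2); }
  std::vector<std::pair<double, int> > heap;  // max-heap on distance
  for (int i = 0; i < n; ++i) {
    heap.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = x[j] - x[i], dy = y[j] - y[i], dz = z[j] - z[i];
      const double dd = dx * dx + dy * dy + dz * dz;
      if ((int)heap.size() < k) {
        heap.push_back(std::make_pair(dd, j));
        std::push_heap(heap.begin(), heap.end());
      } else if (dd < heap.front().first) {
        std::pop_heap(heap.begin(), heap.end());
        heap.back() = std::make_pair(dd, j);
        std::push_heap(heap.begin(), heap.end());
      }
    }
    std::sort_heap(heap.begin(), heap.end());
    for (int m = 0; m < k; ++m) {
      idx(i, m) = heap[m].second + 1;
      dist(i, m) = std::sqrt(heap[m].first);
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}

// ---------------------------------------------------------------------------
// Exact earth mover's distance between equal-size point sets: minimum-cost
// perfect matching on the Euclidean cost matrix via the Hungarian algorithm
// (shortest augmenting paths with potentials, O(n^3)). Returns the mean
// per-point assignment cost.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
double emd_cpp(NumericMatrix A, NumericMatrix B) {
  const int n = A.nrow();
  if (B.nrow() != n) stop("EMD requires equal cardinality");
  std::vector<double> cost((size_t)n * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      const double dx = A(i, 0) - B(j, 0), dy = A(i, 1) - B(j, 1), dz = A(i, 2) - B(j, 2);
      cost[(size_t)i * n + j] = std::sqrt(dx * dx + dy * dy + dz * dz);
    }
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(n + 1, INF);
    std::vector<char> used(n + 1, 0);
    do {
      used[j0] = 1;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= n; ++j) {
        if (used[j]) continue;
        double cur = cost[(size_t)(i0 - 1) * n + (j - 1)] - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  double total = 0.0;
  for (int j = 1; j <= n; ++j) total += cost[(size_t)(p[j] - 1) * n + (j - 1)];
  return total / n;
}
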