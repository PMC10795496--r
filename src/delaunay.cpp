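// Incremental 2D Delaunay triangulation (Bowyer-Watson) with walk-based
// point location. Used by the 2.5D surface reconstruction: points are
// projected to the best-fit plane in R, triangulated here, and the
// connectivity lifted back to 3D.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <utility>
#include <vector>
#include <map>
using namespace Rcpp;

namespace {

struct Tri {
  int v[3];    // CCW vertex indices
  int adj[3];  // adj[i] = triangle across edge opposite v[i], -1 if none
  bool alive;
};

struct Mesh {
  std::vector<double> x, y;
  std::vector<Tri> tris;
  double eps_orient, eps_inc;

  double orient(int a, int b, int c) const {
    return (x[b] - x[a]) * (y[c] - y[a]) - (y[b] - y[a]) * (x[c] - x[a]);
  }
  double orientp(int a, int b, double pxq, double pyq) const {
    return (x[b] - x[a]) * (pyq - y[a]) - (y[b] - y[a]) * (pxq - x[a]);
  }
  // > 0: point d strictly inside circumcircle of CCW triangle (a,b,c)
  double incircle(int a, int b, int c, double dx, double dy) const {
    const double ax = x[a] - dx, ay = y[a] - dy;
    const double bx = x[b] - dx, by = y[b] - dy;
    const double cx = x[c] - dx, cy = y[c] - dy;
    const double a2 = ax * ax + ay * ay, b2 = bx * bx + by * by, c2 = cx * cx + cy * cy;
    return ax * (by * c2 - b2 * cy) - ay * (bx * c2 - b2 * cx) + a2 * (bx * cy - by * cx);
  }

  bool in_tri(int t, double pxq, double pyq) const {
    const Tri& T = tris[t];
    for (int e = 0; e < 3; ++e) {
      int u = T.v[(e + 1) % 3], w = T.v[(e + 2) % 3];
      if (orientp(u, w, pxq, pyq) < -eps_orient) return false;
    }
    return true;
  }

  int locate(int hint, double pxq, double pyq) const {
    int t = hint;
    size_t guard = 4 * tris.size() + 64;
    while (guard--) {
      const Tri& T = tris[t];
      int next = -1;
      for (int e = 0; e < 3; ++e) {
        int u = T.v[(e + 1) % 3], w = T.v[(e + 2) % 3];
        if (orientp(u, w, pxq, pyq) < -eps_orient) { next = T.adj[e]; break; }
      }
      if (next == -1) return t;   // inside (or on boundary of) t
      t = next;
    }
    // numerical trouble: exhaustive fallback
    for (size_t i = 0; i < tris.size(); ++i)
      if (tris[i].alive && in_tri((int)i, pxq, pyq)) return (int)i;
    return -1;
  }
};

}  // namespace

// [[Rcpp::export]]
IntegerMatrix delaunay2d_cpp(NumericVector px, NumericVector py) {
  const int n = px.size();
  if (n < 3) stop("need at least 3 points");
  Mesh M;
  M.x.assign(px.begin(), px.end());
  M.y.assign(py.begin(), py.end());

  double xmin = M.x[0], xmax = M.x[0], ymin = M.y[0], ymax = M.y[0];
  for (int i = 1; i < n; ++i) {
    xmin = std::min(xmin, M.x[i]); xmax = std::max(xmax, M.x[i]);
    ymin = std::min(ymin, M.y[i]); ymax = std::max(ymax, M.y[i]);
  }
  const double span = std::max(xmax - xmin, ymax - ymin);
  if (span <= 0) stop("all points coincide");
  M.eps_orient = 1e-12 * span * span;
  M.eps_inc = 1e-10 * span * span * span * span;

  // finite super-triangle well outside the data
  const double cx = 0.5 * (xmin + xmax), cy = 0.5 * (ymin + ymax);
  const double m = 64.0 * span + 1.0;
  M.x.push_back(cx - 2.0 * m); M.y.push_back(cy - m);
  M.x.push_back(cx + 2.0 * m); M.y.push_back(cy - m);
  M.x.push_back(cx);           M.y.push_back(cy + 2.0 * m);
  Tri super;
  super.v[0] = n; super.v[1] = n + 1; super.v[2] = n + 2;
  super.adj[0] = super.adj[1] = super.adj[2] = -1;
  super.alive = true;
  M.tris.push_back(super);

  // deterministic pseudo-random insertion order (expected O(n log n) walks)
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  unsigned long long s = 88172645463325252ULL;
  for (int i = n - 1; i > 0; --i) {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    int j = (int)(s % (unsigned long long)(i + 1));
    std::swap(order[i], order[j]);
  }

  int hint = 0;
  std::vector<int> cavity, stack;
  std::vector<char> incav;
  for (int oi = 0; oi < n; ++oi) {
    const int p = order[oi];
    const double pxq = M.x[p], pyq = M.y[p];
    int t0 = M.locate(hint, pxq, pyq);
    if (t0 < 0) continue;  // unlocatable (duplicate/degenerate); skip point

    // grow cavity of circumcircle-violating triangles by BFS
    incav.assign(M.tris.size(), 0);
    cavity.clear(); stack.clear();
    stack.push_back(t0); incav[t0] = 1;
    while (!stack.empty()) {
      int t = stack.back(); stack.pop_back();
      cavity.push_back(t);
      for (int e = 0; e < 3; ++e) {
        int nb = M.tris[t].adj[e];
        if (nb < 0 || incav[nb]) continue;
        const Tri& N = M.tris[nb];
        if (M.incircle(N.v[0], N.v[1], N.v[2], pxq, pyq) > M.eps_inc) {
          incav[nb] = 1;
          stack.push_back(nb);
        }
      }
    }

    // boundary edges of the cavity, in the orientation of their cavity tri
    struct BEdge { int u, w, outer, outer_slot; };
    std::vector<BEdge> bed;
    bool valid = true;
    for (size_t ci = 0; ci < cavity.size() && valid; ++ci) {
      int t = cavity[ci];
      for (int e = 0; e < 3; ++e) {
        int nb = M.tris[t].adj[e];
        if (nb >= 0 && incav[nb]) continue;
        BEdge be;
        be.u = M.tris[t].v[(e + 1) % 3];
        be.w = M.tris[t].v[(e + 2) % 3];
        be.outer = nb;
        be.outer_slot = -1;
        if (nb >= 0) {
          for (int f = 0; f < 3; ++f)
            if (M.tris[nb].adj[f] == t) be.outer_slot = f;
          if (be.outer_slot < 0) valid = false;
        }
        bed.push_back(be);
      }
    }
    if (!valid || bed.size() < 3) {
      // conservative fallback: only split the containing triangle
      incav.assign(M.tris.size(), 0);
      cavity.assign(1, t0); incav[t0] = 1;
      bed.clear();
      for (int e = 0; e < 3; ++e) {
        BEdge be;
        be.u = M.tris[t0].v[(e + 1) % 3];
        be.w = M.tris[t0].v[(e + 2) % 3];
        be.outer = M.tris[t0].adj[e];
        be.outer_slot = -1;
        if (be.outer >= 0)
          for (int f = 0; f < 3; ++f)
            if (M.tris[be.outer].adj[f] == t0) be.outer_slot = f;
        bed.push_back(be);
      }
    }

    for (size_t ci = 0; ci < cavity.size(); ++ci) M.tris[cavity[ci]].alive = false;

    // fan of new triangles (u, w, p); link siblings through shared p-edges
    std::map<int, std::pair<int, int> > open;  // other vertex -> (tri, slot)
    int first_new = -1;
    for (size_t bi = 0; bi < bed.size(); ++bi) {
      Tri T;
      T.v[0] = bed[bi].u; T.v[1] = bed[bi].w; T.v[2] = p;
      T.adj[0] = -1; T.adj[1] = -1; T.adj[2] = bed[bi].outer;
      T.alive = true;
      int id = (int)M.tris.size();
      M.tris.push_back(T);
      if (first_new < 0) first_new = id;
      if (bed[bi].outer >= 0 && bed[bi].outer_slot >= 0)
        M.tris[bed[bi].outer].adj[bed[bi].outer_slot] = id;
      // edge opposite v[0]=u is (w,p); edge opposite v[1]=w is (p,u)
      const int others[2] = { bed[bi].w, bed[bi].u };
      for (int sslot = 0; sslot < 2; ++sslot) {
        int ov = others[sslot];
        std::map<int, std::pair<int, int> >::iterator it = open.find(ov);
        if (it == open.end()) {
          open[ov] = std::make_pair(id, sslot);
        } else {
          M.tris[id].adj[sslot] = it->second.first;
          M.tris[it->second.first].adj[it->second.second] = id;
          open.erase(it);
        }
      }
    }
    hint = first_new;
  }

  // collect triangles not touching the super-triangle, CCW, non-degenerate
  std::vector<int> keep;
  for (size_t i = 0; i < M.tris.size(); ++i) {
    if (!M.tris[i].alive) continue;
    const Tri& T = M.tris[i];
    if (T.v[0] >= n || T.v[1] >= n || T.v[2] >= n) continue;
    if (std::fabs(M.orient(T.v[0], T.v[1], T.v[2])) <= M.eps_orient) continue;
    keep.push_back((int)i);
  }
  IntegerMatrix out((int)keep.size(), 3);
  for (size_t i = 0; i < keep.size(); ++i) {
    const Tri& T = M.tris[keep[i]];
    out((int)i, 0) = T.v[0] + 1;
    out((int)i, 1) = T.v[1] + 1;
    out((int)i, 2) = T.v[2] + 1;
  }
  return out;
}
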