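// Incremental (Bowyer-Watson) 3D Delaunay tetrahedralization and the
// alpha-complex volume built on it: tetrahedra whose circumradius is at
// most alpha are kept and their volumes summed. alpha = Inf reduces to
// the convex-hull volume.
//
// Predicates are evaluated on a centered, deterministically jittered copy
// of the coordinates (jitter ~1e-10 of the extent) to sidestep exact
// degeneracies; volumes and circumradii are computed from the original
// coordinates, so closed-form cases stay exact.

#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

namespace {

struct P3 { double x, y, z; };

inline double orient3d(const P3& a, const P3& b, const P3& c, const P3& d) {
  const double bx = b.x - a.x, by = b.y - a.y, bz = b.z - a.z;
  const double cx = c.x - a.x, cy = c.y - a.y, cz = c.z - a.z;
  const double dx = d.x - a.x, dy = d.y - a.y, dz = d.z - a.z;
  return bx * (cy * dz - cz * dy) - by * (cx * dz - cz * dx) +
         bz * (cx * dy - cy * dx);
}

// circumcenter of tet (a,b,c,d); returns false if nearly flat
inline bool circumsphere(const P3& a, const P3& b, const P3& c, const P3& d,
                         P3& cc, double& r2) {
  const double ax = b.x - a.x, ay = b.y - a.y, az = b.z - a.z;
  const double bx = c.x - a.x, by = c.y - a.y, bz = c.z - a.z;
  const double cx = d.x - a.x, cy = d.y - a.y, cz = d.z - a.z;
  const double det = ax * (by * cz - bz * cy) - ay * (bx * cz - bz * cx) +
                     az * (bx * cy - by * cx);
  const double scale = (ax * ax + ay * ay + az * az) +
                       (bx * bx + by * by + bz * bz) +
                       (cx * cx + cy * cy + cz * cz);
  if (std::fabs(det) < 1e-14 * scale * std::sqrt(scale) + 1e-300) return false;
  const double ra = 0.5 * (ax * ax + ay * ay + az * az);
  const double rb = 0.5 * (bx * bx + by * by + bz * bz);
  const double rc = 0.5 * (cx * cx + cy * cy + cz * cz);
  const double ux = (ra * (by * cz - bz * cy) - ay * (rb * cz - rc * bz) +
                     az * (rb * cy - rc * by)) / det;
  const double uy = (ax * (rb * cz - rc * bz) - ra * (bx * cz - bz * cx) +
                     az * (bx * rc - cx * rb)) / det;
  const double uz = (ax * (by * rc - cy * rb) - ay * (bx * rc - cx * rb) +
                     ra * (bx * cy - by * cx)) / det;
  cc.x = a.x + ux; cc.y = a.y + uy; cc.z = a.z + uz;
  r2 = ux * ux + uy * uy + uz * uz;
  return true;
}

struct Tet {
  int v[4];
  int nb[4];      // nb[f]: tet across the face opposite v[f]; -1 = none
  bool alive;
  bool has_sphere;
  P3 cc;
  double r2;
};

struct Triangulation {
  std::vector<P3> pt;       // working (jittered) coords, super verts last
  std::vector<Tet> tets;
  int n;                    // number of real points

  bool in_sphere(int t, const P3& p) {
    Tet& T = tets[t];
    if (!T.has_sphere) {
      T.has_sphere = circumsphere(pt[T.v[0]], pt[T.v[1]], pt[T.v[2]],
                                  pt[T.v[3]], T.cc, T.r2);
      if (!T.has_sphere) T.r2 = R_PosInf;
    }
    if (!std::isfinite(T.r2)) return true; // flat tet: always in cavity
    const double dx = p.x - T.cc.x, dy = p.y - T.cc.y, dz = p.z - T.cc.z;
    return dx * dx + dy * dy + dz * dz <= T.r2 * (1.0 + 1e-12);
  }

  // faces of tet opposite vertex f, ordered positively toward v[f]
  void face_of(int t, int f, int& u0, int& u1, int& u2) {
    static const int F[4][3] = {{1, 3, 2}, {0, 2, 3}, {0, 3, 1}, {0, 1, 2}};
    u0 = tets[t].v[F[f][0]];
    u1 = tets[t].v[F[f][1]];
    u2 = tets[t].v[F[f][2]];
  }

  int locate(int start, const P3& p) {
    int t = start, prev = -1;
    for (long long step = 0; step < (long long)tets.size() * 4 + 64; ++step) {
      int next = -1;
      for (int f = 0; f < 4; ++f) {
        int u0, u1, u2;
        face_of(t, f, u0, u1, u2);
        if (orient3d(pt[u0], pt[u1], pt[u2], p) < 0) {
          const int cand = tets[t].nb[f];
          if (cand >= 0 && cand != prev) { next = cand; break; }
          if (cand >= 0 && next < 0) next = cand;
        }
      }
      if (next < 0) return t;
      prev = t;
      t = next;
    }
    // fallback: linear scan
    for (int i = (int)tets.size() - 1; i >= 0; --i) {
      if (!tets[i].alive) continue;
      bool inside = true;
      for (int f = 0; f < 4 && inside; ++f) {
        int u0, u1, u2;
        face_of(i, f, u0, u1, u2);
        if (orient3d(pt[u0], pt[u1], pt[u2], p) < -1e-300) inside = false;
      }
      if (inside) return i;
    }
    return t;
  }

  void insert(int ip, int& last) {
    const P3 p = pt[ip];
    int t0 = locate(last, p);
    if (!in_sphere(t0, p)) {
      // the located tet must be in the cavity; search neighbours if the
      // walk stopped one off due to a tolerance flip
      bool found = false;
      for (int f = 0; f < 4 && !found; ++f) {
        const int nbh = tets[t0].nb[f];
        if (nbh >= 0 && tets[nbh].alive && in_sphere(nbh, p)) {
          t0 = nbh; found = true;
        }
      }
      if (!found) return; // duplicate/degenerate point: skip
    }
    // cavity BFS
    std::vector<int> cavity, stack;
    std::vector<char> in_cav(tets.size(), 0);
    stack.push_back(t0);
    in_cav[t0] = 1;
    while (!stack.empty()) {
      const int t = stack.back(); stack.pop_back();
      cavity.push_back(t);
      for (int f = 0; f < 4; ++f) {
        const int nbh = tets[t].nb[f];
        if (nbh < 0 || in_cav[nbh] || !tets[nbh].alive) continue;
        if (in_sphere(nbh, p)) { in_cav[nbh] = 1; stack.push_back(nbh); }
      }
    }
    // boundary faces -> new tets
    std::map<std::pair<int, int>, std::pair<int, int> > open_face;
    std::vector<int> fresh;
    for (int t : cavity) {
      for (int f = 0; f < 4; ++f) {
        const int out = tets[t].nb[f];
        if (out >= 0 && in_cav[out]) continue;
        int u0, u1, u2;
        face_of(t, f, u0, u1, u2);
        // the cavity is star-shaped around p and the face is oriented
        // toward the cavity side, so (u0,u1,u2,p) is positively oriented;
        // the swap below is a numerical safety net only
        Tet nt;
        nt.v[0] = u0; nt.v[1] = u1; nt.v[2] = u2; nt.v[3] = ip;
        if (orient3d(pt[nt.v[0]], pt[nt.v[1]], pt[nt.v[2]], pt[nt.v[3]]) < 0)
          std::swap(nt.v[1], nt.v[2]);
        nt.nb[0] = nt.nb[1] = nt.nb[2] = -1;
        nt.nb[3] = out;
        nt.alive = true;
        nt.has_sphere = false;
        const int id = (int)tets.size();
        tets.push_back(nt);
        in_cav.push_back(0);
        fresh.push_back(id);
        if (out >= 0) { // repoint the outside neighbour at the new tet
          for (int g = 0; g < 4; ++g)
            if (tets[out].nb[g] == t) { tets[out].nb[g] = id; break; }
        }
        // link the three faces that contain p with sibling new tets
        for (int e = 0; e < 3; ++e) {
          const int a = tets[id].v[e == 0 ? 1 : 0];
          const int b = tets[id].v[e == 2 ? 1 : 2];
          std::pair<int, int> k(std::min(a, b), std::max(a, b));
          auto it = open_face.find(k);
          if (it == open_face.end()) {
            open_face[k] = std::make_pair(id, e);
          } else {
            tets[id].nb[e] = it->second.first;
            tets[it->second.first].nb[it->second.second] = id;
            open_face.erase(it);
          }
        }
      }
    }
    for (int t : cavity) tets[t].alive = false;
    if (!fresh.empty()) last = fresh.back();
  }
};

// deterministic per-index jitter in [-1,1]
inline double hash_unit(uint64_t h) {
  h ^= h >> 33; h *= 0xff51afd7ed558ccdULL;
  h ^= h >> 33; h *= 0xc4ceb9fe1a85ec53ULL;
  h ^= h >> 33;
  return (double)(h & 0xfffffffffULL) / (double)0xfffffffffULL * 2.0 - 1.0;
}

void build(const NumericMatrix& pts, Triangulation& tri,
           std::vector<P3>& orig) {
  const int n = pts.nrow();
  tri.n = n;
  double mn[3] = {R_PosInf, R_PosInf, R_PosInf};
  double mx[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      if (pts(i, d) < mn[d]) mn[d] = pts(i, d);
      if (pts(i, d) > mx[d]) mx[d] = pts(i, d);
    }
  double span = 1e-9;
  for (int d = 0; d < 3; ++d) span = std::max(span, mx[d] - mn[d]);
  const double cx = 0.5 * (mn[0] + mx[0]), cy = 0.5 * (mn[1] + mx[1]),
               cz = 0.5 * (mn[2] + mx[2]);
  orig.resize(n);
  tri.pt.resize(n + 4);
  const double jit = 1e-10 * span;
  for (int i = 0; i < n; ++i) {
    orig[i].x = pts(i, 0) - cx;
    orig[i].y = pts(i, 1) - cy;
    orig[i].z = pts(i, 2) - cz;
    tri.pt[i].x = orig[i].x + jit * hash_unit(3 * (uint64_t)i + 1);
    tri.pt[i].y = orig[i].y + jit * hash_unit(3 * (uint64_t)i + 2);
    tri.pt[i].z = orig[i].z + jit * hash_unit(3 * (uint64_t)i + 3);
  }
  const double R = 1000.0 * span;
  tri.pt[n + 0].x = 0.0;       tri.pt[n + 0].y = 0.0;      tri.pt[n + 0].z = 3.0 * R;
  tri.pt[n + 1].x = 2.83 * R;  tri.pt[n + 1].y = 0.0;      tri.pt[n + 1].z = -R;
  tri.pt[n + 2].x = -1.41 * R; tri.pt[n + 2].y = 2.45 * R; tri.pt[n + 2].z = -R;
  tri.pt[n + 3].x = -1.41 * R; tri.pt[n + 3].y = -2.45 * R; tri.pt[n + 3].z = -R;
  Tet root;
  root.v[0] = n; root.v[1] = n + 1; root.v[2] = n + 2; root.v[3] = n + 3;
  if (orient3d(tri.pt[root.v[0]], tri.pt[root.v[1]], tri.pt[root.v[2]],
               tri.pt[root.v[3]]) < 0)
    std::swap(root.v[2], root.v[3]);
  root.nb[0] = root.nb[1] = root.nb[2] = root.nb[3] = -1;
  root.alive = true;
  root.has_sphere = false;
  tri.tets.push_back(root);
  // spatially sorted insertion order keeps walks short
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  const double cell = span / std::max(1.0, std::cbrt((double)n));
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    const long long ka[3] = {
        (long long)std::floor(tri.pt[a].x / cell),
        (long long)std::floor(tri.pt[a].y / cell),
        (long long)std::floor(tri.pt[a].z / cell)};
    const long long kb[3] = {
        (long long)std::floor(tri.pt[b].x / cell),
        (long long)std::floor(tri.pt[b].y / cell),
        (long long)std::floor(tri.pt[b].z / cell)};
    if (ka[2] != kb[2]) return ka[2] < kb[2];
    if (ka[1] != kb[1]) return ka[1] < kb[1];
    if (ka[0] != kb[0]) return ka[0] < kb[0];
    return a < b;
  });
  int last = 0;
  for (int i : order) tri.insert(i, last);
}

inline double tet_volume(const P3& a, const P3& b, const P3& c, const P3& d) {
  return std::fabs(orient3d(a, b, c, d)) / 6.0;
}

} // namespace

// [[Rcpp::export(name = ".alpha_volume_cpp")]]
NumericVector alpha_volume_cpp(NumericMatrix pts, NumericVector alphas) {
  Triangulation tri;
  std::vector<P3> orig;
  build(pts, tri, orig);
  const int n = tri.n;
  NumericVector out(alphas.size());
  for (const Tet& t : tri.tets) {
    if (!t.alive) continue;
    if (t.v[0] >= n || t.v[1] >= n || t.v[2] >= n || t.v[3] >= n) continue;
    const P3 &a = orig[t.v[0]], &b = orig[t.v[1]], &c = orig[t.v[2]],
             &d = orig[t.v[3]];
    P3 cc;
    double r2;
    const bool ok = circumsphere(a, b, c, d, cc, r2);
    const double vol = tet_volume(a, b, c, d);
    for (int k = 0; k < alphas.size(); ++k) {
      const double alpha = alphas[k];
      if (!std::isfinite(alpha)) { out[k] += vol; continue; }
      if (ok && r2 <= alpha * alpha) out[k] += vol;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".delaunay_tets_cpp")]]
IntegerMatrix delaunay_tets_cpp(NumericMatrix pts) {
  Triangulation tri;
  std::vector<P3> orig;
  build(pts, tri, orig);
  const int n = tri.n;
  std::vector<const Tet*> keep;
  for (const Tet& t : tri.tets) {
    if (!t.alive) continue;
    if (t.v[0] >= n || t.v[1] >= n || t.v[2] >= n || t.v[3] >= n) continue;
    keep.push_back(&t);
  }
  IntegerMatrix out((int)keep.size(), 4);
  for (int i = 0; i < (int)keep.size(); ++i)
    for (int j = 0; j < 4; ++j) out(i, j) = keep[i]->v[j] + 1;
  return out;
}
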