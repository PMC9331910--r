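// Incremental Bowyer-Watson Delaunay tetrahedralization with walking point
// location and cached circumspheres. Input is expected to be pre-jittered by
// the R wrapper to break exact degeneracies (cospherical / coplanar sets).
#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
#include <cstdlib>
using namespace Rcpp;

namespace {

struct Tet {
  int v[4];
  int nb[4];      // nb[k]: tet sharing the face opposite v[k], -1 if none
  double cx, cy, cz, r2; // cached circumsphere
  bool alive;
};

struct Mesh {
  std::vector<double> px, py, pz;
  std::vector<Tet> tets;
  double orientTol;

  double orient(int a, int b, int c, int d) const {
    double adx = px[a]-px[d], ady = py[a]-py[d], adz = pz[a]-pz[d];
    double bdx = px[b]-px[d], bdy = py[b]-py[d], bdz = pz[b]-pz[d];
    double cdx = px[c]-px[d], cdy = py[c]-py[d], cdz = pz[c]-pz[d];
    return adx*(bdy*cdz - bdz*cdy) - ady*(bdx*cdz - bdz*cdx) + adz*(bdx*cdy - bdy*cdx);
  }

  // circumsphere via Cramer's rule on 2(B-A),2(C-A),2(D-A)
  bool circumsphere(Tet& t) {
    int a = t.v[0], b = t.v[1], c = t.v[2], d = t.v[3];
    double m[3][3], rhs[3];
    double ax = px[a], ay = py[a], az = pz[a];
    int vv[3] = {b, c, d};
    for (int i = 0; i < 3; ++i) {
      double x = px[vv[i]], y = py[vv[i]], z = pz[vv[i]];
      m[i][0] = 2*(x-ax); m[i][1] = 2*(y-ay); m[i][2] = 2*(z-az);
      rhs[i] = (x*x - ax*ax) + (y*y - ay*ay) + (z*z - az*az);
    }
    double det = m[0][0]*(m[1][1]*m[2][2]-m[1][2]*m[2][1])
               - m[0][1]*(m[1][0]*m[2][2]-m[1][2]*m[2][0])
               + m[0][2]*(m[1][0]*m[2][1]-m[1][1]*m[2][0]);
    if (det == 0.0) return false;
    double inv = 1.0/det;
    double cx = inv*( rhs[0]*(m[1][1]*m[2][2]-m[1][2]*m[2][1])
                    - m[0][1]*(rhs[1]*m[2][2]-m[1][2]*rhs[2])
                    + m[0][2]*(rhs[1]*m[2][1]-m[1][1]*rhs[2]));
    double cy = inv*( m[0][0]*(rhs[1]*m[2][2]-m[1][2]*rhs[2])
                    - rhs[0]*(m[1][0]*m[2][2]-m[1][2]*m[2][0])
                    + m[0][2]*(m[1][0]*rhs[2]-rhs[1]*m[2][0]));
    double cz = inv*( m[0][0]*(m[1][1]*rhs[2]-rhs[1]*m[2][1])
                    - m[0][1]*(m[1][0]*rhs[2]-rhs[1]*m[2][0])
                    + rhs[0]*(m[1][0]*m[2][1]-m[1][1]*m[2][0]));
    t.cx = cx; t.cy = cy; t.cz = cz;
    double dx = cx-ax, dy = cy-ay, dz = cz-az;
    t.r2 = dx*dx + dy*dy + dz*dz;
    return true;
  }

  bool inSphere(const Tet& t, int p) const {
    double dx = px[p]-t.cx, dy = py[p]-t.cy, dz = pz[p]-t.cz;
    return dx*dx + dy*dy + dz*dz < t.r2 * (1.0 - 1e-14);
  }

  // vertices of the face opposite slot k, in a fixed order
  void faceVerts(const Tet& t, int k, int f[3]) const {
    int j = 0;
    for (int i = 0; i < 4; ++i) if (i != k) f[j++] = t.v[i];
  }

  int locate(int p, int hint, bool& ok) {
    int cur = hint, steps = 0;
    int limit = (int)tets.size() * 4 + 1000;
    while (steps++ < limit) {
      const Tet& t = tets[cur];
      bool moved = false;
      for (int k = 0; k < 4; ++k) {
        int f[3]; faceVerts(t, k, f);
        double sp = orient(f[0], f[1], f[2], p);
        double sref = orient(f[0], f[1], f[2], t.v[k]);
        if (sref > 0 ? (sp < -orientTol) : (sp > orientTol)) {
          if (t.nb[k] < 0) { ok = false; return cur; }
          cur = t.nb[k]; moved = true; break;
        }
      }
      if (!moved) { ok = true; return cur; }
    }
    ok = false; return cur;
  }

  void makePositive(Tet& t) {
    if (orient(t.v[0], t.v[1], t.v[2], t.v[3]) < 0) std::swap(t.v[2], t.v[3]);
  }
};

} // namespace

// [[Rcpp::export(name = ".delaunay_cpp")]]
List delaunay_cpp(NumericMatrix P) {
  const int n = P.nrow();
  if (n < 4) stop("Delaunay tetrahedralization needs at least 4 points");

  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) lo[d] = hi[d] = P(0,d);
  for (int i = 1; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      if (P(i,d) < lo[d]) lo[d] = P(i,d);
      if (P(i,d) > hi[d]) hi[d] = P(i,d);
    }
  double diag = std::sqrt((hi[0]-lo[0])*(hi[0]-lo[0]) + (hi[1]-lo[1])*(hi[1]-lo[1]) +
                          (hi[2]-lo[2])*(hi[2]-lo[2]));
  if (diag <= 0) stop("degenerate geometry: all points coincide");

  Mesh M;
  M.px.resize(n + 4); M.py.resize(n + 4); M.pz.resize(n + 4);
  for (int i = 0; i < n; ++i) { M.px[i] = P(i,0); M.py[i] = P(i,1); M.pz[i] = P(i,2); }
  M.orientTol = 1e-12 * diag * diag * diag;

  // super-tetrahedron: regular, circumradius R about the bbox center
  double cx = (lo[0]+hi[0])/2, cy = (lo[1]+hi[1])/2, cz = (lo[2]+hi[2])/2;
  double R = 2000.0 * diag;
  double s = R / std::sqrt(3.0);
  double sv[4][3] = {{ s,  s,  s}, { s, -s, -s}, {-s,  s, -s}, {-s, -s,  s}};
  for (int k = 0; k < 4; ++k) {
    M.px[n+k] = cx + sv[k][0]; M.py[n+k] = cy + sv[k][1]; M.pz[n+k] = cz + sv[k][2];
  }
  Tet t0; t0.v[0]=n; t0.v[1]=n+1; t0.v[2]=n+2; t0.v[3]=n+3;
  for (int k = 0; k < 4; ++k) t0.nb[k] = -1;
  t0.alive = true;
  M.makePositive(t0);
  if (!M.circumsphere(t0)) stop("internal error: degenerate super-tetrahedron");
  M.tets.push_back(t0);

  int hint = 0;
  std::vector<int> cavity, stack;
  std::vector<char> inCav;

  for (int p = 0; p < n; ++p) {
    bool ok = false;
    int seed = M.locate(p, hint, ok);
    if (!ok) {
      // fallback: exhaustive scan for a tet whose circumsphere holds p
      seed = -1;
      for (size_t t = 0; t < M.tets.size(); ++t)
        if (M.tets[t].alive && M.inSphere(M.tets[t], p)) { seed = (int)t; break; }
      if (seed < 0) stop("point location failed (degenerate input?) at point %d", p + 1);
    }
    // BFS cavity
    cavity.clear(); stack.clear();
    inCav.assign(M.tets.size(), 0);
    stack.push_back(seed); inCav[seed] = 1;
    while (!stack.empty()) {
      int t = stack.back(); stack.pop_back();
      cavity.push_back(t);
      for (int k = 0; k < 4; ++k) {
        int o = M.tets[t].nb[k];
        if (o >= 0 && !inCav[o] && M.tets[o].alive && M.inSphere(M.tets[o], p)) {
          inCav[o] = 1; stack.push_back(o);
        }
      }
    }
    // boundary faces -> new tets
    std::map<std::pair<int,int>, std::pair<int,int>> edgeMap; // sorted edge -> (tet, slot)
    std::vector<int> fresh;
    for (size_t ci = 0; ci < cavity.size(); ++ci) {
      int t = cavity[ci];
      for (int k = 0; k < 4; ++k) {
        int o = M.tets[t].nb[k];
        if (o >= 0 && inCav[o]) continue; // interior face
        int f[3]; M.faceVerts(M.tets[t], k, f);
        Tet nt;
        nt.v[0] = f[0]; nt.v[1] = f[1]; nt.v[2] = f[2]; nt.v[3] = p;
        nt.alive = true;
        M.makePositive(nt);
        if (!M.circumsphere(nt))
          stop("degenerate tetrahedron during insertion of point %d", p + 1);
        for (int j = 0; j < 4; ++j) nt.nb[j] = -1;
        int idx = (int)M.tets.size();
        // neighbor across the base face is the old outside tet
        int slotP = -1;
        for (int j = 0; j < 4; ++j) if (nt.v[j] == p) slotP = j;
        nt.nb[slotP] = o;
        if (o >= 0) {
          for (int j = 0; j < 4; ++j) if (M.tets[o].nb[j] == t) { M.tets[o].nb[j] = idx; break; }
        }
        M.tets.push_back(nt);
        fresh.push_back(idx);
        // link faces containing p via shared base edges
        for (int e = 0; e < 3; ++e) {
          int u = f[e], v = f[(e+1)%3];
          std::pair<int,int> key(std::min(u,v), std::max(u,v));
          // slot of the base vertex NOT on this edge (the face (u,v,p) is opposite it)
          int w = f[(e+2)%3];
          int slotW = -1;
          for (int j = 0; j < 4; ++j) if (M.tets[idx].v[j] == w) slotW = j;
          std::map<std::pair<int,int>, std::pair<int,int>>::iterator it = edgeMap.find(key);
          if (it == edgeMap.end()) {
            edgeMap[key] = std::make_pair(idx, slotW);
          } else {
            int other = it->second.first, oslot = it->second.second;
            M.tets[idx].nb[slotW] = other;
            M.tets[other].nb[oslot] = idx;
          }
        }
      }
    }
    for (size_t ci = 0; ci < cavity.size(); ++ci) M.tets[cavity[ci]].alive = false;
    if (!fresh.empty()) hint = fresh.back();
  }

  // collect tets without super vertices
  std::vector<int> keep;
  for (size_t t = 0; t < M.tets.size(); ++t) {
    if (!M.tets[t].alive) continue;
    bool super = false;
    for (int k = 0; k < 4; ++k) if (M.tets[t].v[k] >= n) super = true;
    if (!super) keep.push_back((int)t);
  }
  int m = (int)keep.size();
  IntegerMatrix TT(m, 4);
  NumericVector crad(m), vol(m);
  for (int r = 0; r < m; ++r) {
    const Tet& t = M.tets[keep[r]];
    for (int k = 0; k < 4; ++k) TT(r,k) = t.v[k] + 1;
    crad[r] = std::sqrt(t.r2);
    vol[r] = M.orient(t.v[0], t.v[1], t.v[2], t.v[3]) / 6.0; // positive by construction
  }
  return List::create(_["tets"] = TT, _["circumradius"] = crad, _["volume"] = vol);
}
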