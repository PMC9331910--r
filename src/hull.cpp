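// Incremental 3D convex hull (quickhull-style point insertion).
// Faces are kept with outward orientation relative to an interior point.
#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
using namespace Rcpp;

namespace {

struct Face {
  int a, b, c;       // vertex indices, outward CCW winding
  double nx, ny, nz; // outward normal (not normalized)
  double off;        // plane offset: n . x = off
  bool alive;
};

inline void faceNormal(const NumericMatrix& P, Face& f) {
  double ux = P(f.b,0)-P(f.a,0), uy = P(f.b,1)-P(f.a,1), uz = P(f.b,2)-P(f.a,2);
  double vx = P(f.c,0)-P(f.a,0), vy = P(f.c,1)-P(f.a,1), vz = P(f.c,2)-P(f.a,2);
  f.nx = uy*vz - uz*vy;
  f.ny = uz*vx - ux*vz;
  f.nz = ux*vy - uy*vx;
  f.off = f.nx*P(f.a,0) + f.ny*P(f.a,1) + f.nz*P(f.a,2);
}

inline double planeEval(const Face& f, double x, double y, double z) {
  return f.nx*x + f.ny*y + f.nz*z - f.off;
}

} // namespace

// [[Rcpp::export(name = ".convex_hull_cpp")]]
List convex_hull_cpp(NumericMatrix P) {
  const int n = P.nrow();
  if (n < 4) stop("convex hull needs at least 4 points");

  // bounding-box scale for tolerances
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) { lo[d] = hi[d] = P(0,d); }
  for (int i = 1; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      if (P(i,d) < lo[d]) lo[d] = P(i,d);
      if (P(i,d) > hi[d]) hi[d] = P(i,d);
    }
  double diag = std::sqrt((hi[0]-lo[0])*(hi[0]-lo[0]) + (hi[1]-lo[1])*(hi[1]-lo[1]) +
                          (hi[2]-lo[2])*(hi[2]-lo[2]));
  if (diag <= 0) stop("degenerate geometry: all points coincide");
  const double eps = 1e-10 * diag;

  // initial tetrahedron from extreme points
  int i0 = 0, i1 = 0;
  for (int i = 0; i < n; ++i) { // extremes along x, fall back to max pairwise of axis extremes
    if (P(i,0) < P(i0,0)) i0 = i;
    if (P(i,0) > P(i1,0)) i1 = i;
  }
  if (i0 == i1) { i0 = 0; i1 = 1; }
  // farthest from segment i0-i1
  int i2 = -1; double best = eps;
  double ax = P(i0,0), ay = P(i0,1), az = P(i0,2);
  double dx = P(i1,0)-ax, dy = P(i1,1)-ay, dz = P(i1,2)-az;
  double dlen2 = dx*dx + dy*dy + dz*dz;
  if (dlen2 <= 0) stop("degenerate geometry: extreme points coincide");
  for (int i = 0; i < n; ++i) {
    double px = P(i,0)-ax, py = P(i,1)-ay, pz = P(i,2)-az;
    double cx = py*dz - pz*dy, cy = pz*dx - px*dz, cz = px*dy - py*dx;
    double d2 = (cx*cx + cy*cy + cz*cz) / dlen2;
    if (d2 > best*best) { best = std::sqrt(d2); i2 = i; }
  }
  if (i2 < 0) stop("degenerate geometry: points are collinear");
  // farthest from plane i0,i1,i2
  Face base; base.a = i0; base.b = i1; base.c = i2; faceNormal(P, base);
  int i3 = -1; best = eps;
  for (int i = 0; i < n; ++i) {
    double d = std::fabs(planeEval(base, P(i,0), P(i,1), P(i,2)));
    double nn = std::sqrt(base.nx*base.nx + base.ny*base.ny + base.nz*base.nz);
    if (nn > 0 && d/nn > best) { best = d/nn; i3 = i; }
  }
  if (i3 < 0) stop("degenerate geometry: points are coplanar");

  double icx = (P(i0,0)+P(i1,0)+P(i2,0)+P(i3,0))/4.0;
  double icy = (P(i0,1)+P(i1,1)+P(i2,1)+P(i3,1))/4.0;
  double icz = (P(i0,2)+P(i1,2)+P(i2,2)+P(i3,2))/4.0;

  std::vector<Face> faces;
  int tet[4][3] = {{i0,i1,i2},{i0,i1,i3},{i0,i2,i3},{i1,i2,i3}};
  for (int t = 0; t < 4; ++t) {
    Face f; f.a = tet[t][0]; f.b = tet[t][1]; f.c = tet[t][2]; f.alive = true;
    faceNormal(P, f);
    if (planeEval(f, icx, icy, icz) > 0) { std::swap(f.b, f.c); faceNormal(P, f); }
    faces.push_back(f);
  }

  // incremental insertion
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2 || i == i3) continue;
    double x = P(i,0), y = P(i,1), z = P(i,2);
    std::vector<int> vis;
    for (size_t f = 0; f < faces.size(); ++f) {
      if (!faces[f].alive) continue;
      double nn = std::sqrt(faces[f].nx*faces[f].nx + faces[f].ny*faces[f].ny +
                            faces[f].nz*faces[f].nz);
      if (nn <= 0) continue;
      if (planeEval(faces[f], x, y, z) / nn > eps) vis.push_back((int)f);
    }
    if (vis.empty()) continue; // interior point

    // horizon: directed edges of visible faces not shared with another visible face
    std::map<std::pair<int,int>, int> edgeCount;
    for (int f : vis) {
      int e[3][2] = {{faces[f].a, faces[f].b}, {faces[f].b, faces[f].c}, {faces[f].c, faces[f].a}};
      for (int k = 0; k < 3; ++k) {
        int u = e[k][0], v = e[k][1];
        std::pair<int,int> key(std::min(u,v), std::max(u,v));
        edgeCount[key]++;
      }
    }
    std::vector<std::pair<int,int>> horizon;
    for (int f : vis) {
      int e[3][2] = {{faces[f].a, faces[f].b}, {faces[f].b, faces[f].c}, {faces[f].c, faces[f].a}};
      for (int k = 0; k < 3; ++k) {
        int u = e[k][0], v = e[k][1];
        std::pair<int,int> key(std::min(u,v), std::max(u,v));
        if (edgeCount[key] == 1) horizon.push_back(std::make_pair(u, v));
      }
    }
    for (int f : vis) faces[f].alive = false;
    for (size_t k = 0; k < horizon.size(); ++k) {
      Face f; f.a = horizon[k].first; f.b = horizon[k].second; f.c = i; f.alive = true;
      faceNormal(P, f);
      if (planeEval(f, icx, icy, icz) > 0) { std::swap(f.b, f.c); faceNormal(P, f); }
      faces.push_back(f);
    }
  }

  int m = 0;
  for (size_t f = 0; f < faces.size(); ++f) if (faces[f].alive) ++m;
  IntegerMatrix F(m, 3);
  int r = 0;
  for (size_t f = 0; f < faces.size(); ++f) {
    if (!faces[f].alive) continue;
    F(r,0) = faces[f].a + 1; F(r,1) = faces[f].b + 1; F(r,2) = faces[f].c + 1;
    ++r;
  }
  return List::create(_["faces"] = F);
}
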