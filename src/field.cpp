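// Regular-grid Poisson indicator-field machinery:
//   - Gaussian splatting of oriented samples into a node vector field
//   - central-difference divergence
//   - matrix-free conjugate-gradient solve of the discrete Poisson equation
//     (7-point Laplacian, homogeneous Dirichlet boundary)
//   - trilinear sampling of the solved field at arbitrary points
//   - marching-tetrahedra isosurface extraction (6-tet Kuhn cube split,
//     welded vertices, orientation consistent with the field gradient)
#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
using namespace Rcpp;

namespace {
inline long idx3(int i, int j, int k, int nx, int ny) { return i + nx * (j + (long)ny * k); }

// conjugate gradients for -Laplacian x = b (7-point stencil, homogeneous
// Dirichlet boundary), warm-started from x
void cgSolve(const std::vector<double>& b, int nx, int ny, int nz, double h,
             double tol, int maxit, std::vector<double>& x) {
  const long nn = (long)nx * ny * nz;
  const double h2 = h * h;
  std::vector<double> r(nn, 0.0), p(nn, 0.0), Ap(nn, 0.0);
  // r = b - A x on interior nodes; boundary stays clamped at 0
  for (int k = 1; k < nz-1; ++k)
    for (int j = 1; j < ny-1; ++j)
      for (int i = 1; i < nx-1; ++i) {
        long id = idx3(i,j,k,nx,ny);
        double lap = (x[idx3(i+1,j,k,nx,ny)] + x[idx3(i-1,j,k,nx,ny)]
                    + x[idx3(i,j+1,k,nx,ny)] + x[idx3(i,j-1,k,nx,ny)]
                    + x[idx3(i,j,k+1,nx,ny)] + x[idx3(i,j,k-1,nx,ny)]
                    - 6.0 * x[id]) / h2;
        r[id] = b[id] + lap;
        p[id] = r[id];
      }
  double rs = 0.0;
  for (long id = 0; id < nn; ++id) rs += r[id]*r[id];
  double bb = 0.0;
  for (long id = 0; id < nn; ++id) bb += b[id]*b[id];
  if (bb <= 0 || rs <= 0) return;
  const double target = tol * tol * bb;
  for (int it = 0; it < maxit && rs > target; ++it) {
    for (int k = 1; k < nz-1; ++k)
      for (int j = 1; j < ny-1; ++j)
        for (int i = 1; i < nx-1; ++i) {
          long id = idx3(i,j,k,nx,ny);
          double lap = (p[idx3(i+1,j,k,nx,ny)] + p[idx3(i-1,j,k,nx,ny)]
                      + p[idx3(i,j+1,k,nx,ny)] + p[idx3(i,j-1,k,nx,ny)]
                      + p[idx3(i,j,k+1,nx,ny)] + p[idx3(i,j,k-1,nx,ny)]
                      - 6.0 * p[id]) / h2;
          Ap[id] = -lap;
        }
    double pAp = 0.0;
    for (long id = 0; id < nn; ++id) pAp += p[id]*Ap[id];
    if (pAp <= 0) break;
    double alpha = rs / pAp;
    double rsNew = 0.0;
    for (long id = 0; id < nn; ++id) {
      x[id] += alpha * p[id];
      r[id] -= alpha * Ap[id];
      rsNew += r[id]*r[id];
    }
    double beta = rsNew / rs;
    for (long id = 0; id < nn; ++id) p[id] = r[id] + beta * p[id];
    rs = rsNew;
  }
}

// cascadic solve: recursively solve an injected half-resolution problem and
// trilinearly prolong it as the warm start for CG at this level
void cascadeSolve(const std::vector<double>& b, int nx, int ny, int nz,
                  double h, double tol, int maxit, std::vector<double>& x) {
  const long nn = (long)nx * ny * nz;
  x.assign(nn, 0.0);
  if (nx > 48 && ny > 48 && nz > 48) {
    int cx = (nx + 1) / 2, cy = (ny + 1) / 2, cz = (nz + 1) / 2;
    std::vector<double> cb((long)cx * cy * cz, 0.0);
    for (int k = 0; k < cz; ++k)
      for (int j = 0; j < cy; ++j)
        for (int i = 0; i < cx; ++i) {
          int fi = std::min(2*i, nx-1), fj = std::min(2*j, ny-1), fk = std::min(2*k, nz-1);
          cb[idx3(i,j,k,cx,cy)] = b[idx3(fi,fj,fk,nx,ny)];
        }
    std::vector<double> cxs;
    cascadeSolve(cb, cx, cy, cz, 2.0 * h, tol, maxit, cxs);
    // trilinear prolongation (interior only; boundary remains 0)
    for (int k = 1; k < nz-1; ++k)
      for (int j = 1; j < ny-1; ++j)
        for (int i = 1; i < nx-1; ++i) {
          double fx = i / 2.0, fy = j / 2.0, fz = k / 2.0;
          int i0 = std::min((int)fx, cx-2), j0 = std::min((int)fy, cy-2), k0 = std::min((int)fz, cz-2);
          double tx = fx - i0, ty = fy - j0, tz = fz - k0;
          double v = 0.0;
          for (int dk = 0; dk < 2; ++dk)
            for (int dj = 0; dj < 2; ++dj)
              for (int di = 0; di < 2; ++di)
                v += (di ? tx : 1-tx) * (dj ? ty : 1-ty) * (dk ? tz : 1-tz)
                   * cxs[idx3(i0+di, j0+dj, k0+dk, cx, cy)];
          x[idx3(i,j,k,nx,ny)] = v;
        }
  }
  cgSolve(b, nx, ny, nz, h, tol, maxit, x);
}

} // namespace

// [[Rcpp::export(name = ".poisson_field_cpp")]]
NumericVector poisson_field_cpp(NumericMatrix P, NumericMatrix N,
                                NumericVector origin, double h,
                                IntegerVector dims, double sigma,
                                double tol, int maxit) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long nn = (long)nx * ny * nz;
  const int m = P.nrow();
  std::vector<double> Vx(nn, 0.0), Vy(nn, 0.0), Vz(nn, 0.0);

  // splat: V approximates the smoothed gradient of the indicator function;
  // with outward sample normals the gradient points inward, hence the minus
  const double win = 3.0 * sigma;
  for (int s = 0; s < m; ++s) {
    double x = P(s,0), y = P(s,1), z = P(s,2);
    int i0 = std::max(0, (int)std::ceil((x - win - origin[0]) / h));
    int i1 = std::min(nx - 1, (int)std::floor((x + win - origin[0]) / h));
    int j0 = std::max(0, (int)std::ceil((y - win - origin[1]) / h));
    int j1 = std::min(ny - 1, (int)std::floor((y + win - origin[1]) / h));
    int k0 = std::max(0, (int)std::ceil((z - win - origin[2]) / h));
    int k1 = std::min(nz - 1, (int)std::floor((z + win - origin[2]) / h));
    double s2 = sigma * sigma;
    for (int k = k0; k <= k1; ++k) {
      double dz = origin[2] + k*h - z;
      for (int j = j0; j <= j1; ++j) {
        double dy = origin[1] + j*h - y;
        for (int i = i0; i <= i1; ++i) {
          double dx = origin[0] + i*h - x;
          double w = std::exp(-(dx*dx + dy*dy + dz*dz) / s2);
          long id = idx3(i, j, k, nx, ny);
          Vx[id] -= w * N(s,0);
          Vy[id] -= w * N(s,1);
          Vz[id] -= w * N(s,2);
        }
      }
    }
  }

  // b = -div V (so that A chi = b with A = -Laplacian, SPD)
  std::vector<double> b(nn, 0.0);
  for (int k = 1; k < nz-1; ++k)
    for (int j = 1; j < ny-1; ++j)
      for (int i = 1; i < nx-1; ++i) {
        long id = idx3(i,j,k,nx,ny);
        double div = (Vx[idx3(i+1,j,k,nx,ny)] - Vx[idx3(i-1,j,k,nx,ny)]
                    + Vy[idx3(i,j+1,k,nx,ny)] - Vy[idx3(i,j-1,k,nx,ny)]
                    + Vz[idx3(i,j,k+1,nx,ny)] - Vz[idx3(i,j,k-1,nx,ny)]) / (2.0*h);
        b[id] = -div;
      }

  std::vector<double> x;
  cascadeSolve(b, nx, ny, nz, h, tol, maxit, x);

  NumericVector out(nn);
  for (long id = 0; id < nn; ++id) out[id] = x[id];
  out.attr("dim") = dims;
  return out;
}

// [[Rcpp::export(name = ".trilinear_cpp")]]
NumericVector trilinear_cpp(NumericVector field, NumericVector origin, double h,
                            IntegerVector dims, NumericMatrix Q) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int m = Q.nrow();
  NumericVector out(m);
  for (int s = 0; s < m; ++s) {
    double fx = (Q(s,0) - origin[0]) / h;
    double fy = (Q(s,1) - origin[1]) / h;
    double fz = (Q(s,2) - origin[2]) / h;
    int i = std::max(0, std::min(nx-2, (int)std::floor(fx)));
    int j = std::max(0, std::min(ny-2, (int)std::floor(fy)));
    int k = std::max(0, std::min(nz-2, (int)std::floor(fz)));
    double tx = std::max(0.0, std::min(1.0, fx - i));
    double ty = std::max(0.0, std::min(1.0, fy - j));
    double tz = std::max(0.0, std::min(1.0, fz - k));
    double v = 0.0;
    for (int dk = 0; dk < 2; ++dk)
      for (int dj = 0; dj < 2; ++dj)
        for (int di = 0; di < 2; ++di) {
          double w = (di ? tx : 1-tx) * (dj ? ty : 1-ty) * (dk ? tz : 1-tz);
          v += w * field[idx3(i+di, j+dj, k+dk, nx, ny)];
        }
    out[s] = v;
  }
  return out;
}

namespace {

struct MTState {
  std::map<std::pair<long,long>, int> edgeVert;
  std::vector<double> vx, vy, vz;
  std::vector<int> fa, fb, fc;
};

inline int edgePoint(MTState& st, long ga, long gb, double sa, double sb,
                     const double* pa, const double* pb) {
  std::pair<long,long> key(std::min(ga,gb), std::max(ga,gb));
  std::map<std::pair<long,long>, int>::iterator it = st.edgeVert.find(key);
  if (it != st.edgeVert.end()) return it->second;
  double t = sa / (sa - sb);
  if (ga > gb) { /* canonical direction for exact reproducibility */ }
  int id = (int)st.vx.size();
  st.vx.push_back(pa[0] + t*(pb[0]-pa[0]));
  st.vy.push_back(pa[1] + t*(pb[1]-pa[1]));
  st.vz.push_back(pa[2] + t*(pb[2]-pa[2]));
  st.edgeVert[key] = id;
  return id;
}

inline void emitTri(MTState& st, int a, int b, int c, const double* posRef) {
  // orient so the normal points away from the positive (interior) reference
  double ux = st.vx[b]-st.vx[a], uy = st.vy[b]-st.vy[a], uz = st.vz[b]-st.vz[a];
  double wx = st.vx[c]-st.vx[a], wy = st.vy[c]-st.vy[a], wz = st.vz[c]-st.vz[a];
  double nx = uy*wz - uz*wy, ny = uz*wx - ux*wz, nz = ux*wy - uy*wx;
  double cx = (st.vx[a]+st.vx[b]+st.vx[c])/3.0 - posRef[0];
  double cy = (st.vy[a]+st.vy[b]+st.vy[c])/3.0 - posRef[1];
  double cz = (st.vz[a]+st.vz[b]+st.vz[c])/3.0 - posRef[2];
  if (nx*cx + ny*cy + nz*cz < 0) std::swap(b, c);
  st.fa.push_back(a); st.fb.push_back(b); st.fc.push_back(c);
}

} // namespace

// [[Rcpp::export(name = ".marching_tets_cpp")]]
List marching_tets_cpp(NumericVector field, double iso, NumericVector origin,
                       double h, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  // Kuhn split of each cube into 6 tetrahedra around the 0-6 diagonal;
  // the induced face diagonals match between adjacent cubes
  static const int cubeTet[6][4] = {
    {0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6},{0,5,1,6}
  };
  static const int cOff[8][3] = {
    {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}
  };
  // snap threshold relative to field range
  double fmax = 0.0;
  for (R_xlen_t i = 0; i < field.size(); ++i) {
    double a = std::fabs(field[i] - iso);
    if (a > fmax) fmax = a;
  }
  const double snap = (fmax > 0 ? fmax : 1.0) * 1e-12;

  MTState st;
  double pos[8][3]; double sv[8]; long gid[8];
  for (int k = 0; k < nz-1; ++k)
    for (int j = 0; j < ny-1; ++j)
      for (int i = 0; i < nx-1; ++i) {
        bool anyPos = false, anyNeg = false;
        for (int c = 0; c < 8; ++c) {
          int ii = i + cOff[c][0], jj = j + cOff[c][1], kk = k + cOff[c][2];
          gid[c] = idx3(ii, jj, kk, nx, ny);
          double s = field[gid[c]] - iso;
          if (std::fabs(s) < snap) s = snap;
          sv[c] = s;
          pos[c][0] = origin[0] + ii*h; pos[c][1] = origin[1] + jj*h; pos[c][2] = origin[2] + kk*h;
          if (s > 0) anyPos = true; else anyNeg = true;
        }
        if (!anyPos || !anyNeg) continue;
        for (int t = 0; t < 6; ++t) {
          int v[4] = {cubeTet[t][0], cubeTet[t][1], cubeTet[t][2], cubeTet[t][3]};
          int posIdx[4], negIdx[4]; int np = 0, nm = 0;
          for (int q = 0; q < 4; ++q) {
            if (sv[v[q]] > 0) posIdx[np++] = v[q]; else negIdx[nm++] = v[q];
          }
          if (np == 0 || np == 4) continue;
          if (np == 1 || np == 3) {
            int apex = (np == 1) ? posIdx[0] : negIdx[0];
            int rest[3]; int rr = 0;
            for (int q = 0; q < 4; ++q) if (v[q] != apex) rest[rr++] = v[q];
            int e0 = edgePoint(st, gid[apex], gid[rest[0]], sv[apex], sv[rest[0]], pos[apex], pos[rest[0]]);
            int e1 = edgePoint(st, gid[apex], gid[rest[1]], sv[apex], sv[rest[1]], pos[apex], pos[rest[1]]);
            int e2 = edgePoint(st, gid[apex], gid[rest[2]], sv[apex], sv[rest[2]], pos[apex], pos[rest[2]]);
            const double* ref = (np == 1) ? pos[apex] : pos[posIdx[0]];
            emitTri(st, e0, e1, e2, ref);
          } else { // 2-2
            int A = posIdx[0], B = posIdx[1], C = negIdx[0], D = negIdx[1];
            int eAC = edgePoint(st, gid[A], gid[C], sv[A], sv[C], pos[A], pos[C]);
            int eAD = edgePoint(st, gid[A], gid[D], sv[A], sv[D], pos[A], pos[D]);
            int eBD = edgePoint(st, gid[B], gid[D], sv[B], sv[D], pos[B], pos[D]);
            int eBC = edgePoint(st, gid[B], gid[C], sv[B], sv[C], pos[B], pos[C]);
            double mid[3] = {(pos[A][0]+pos[B][0])/2, (pos[A][1]+pos[B][1])/2, (pos[A][2]+pos[B][2])/2};
            emitTri(st, eAC, eAD, eBD, mid);
            emitTri(st, eAC, eBD, eBC, mid);
          }
        }
      }

  int nv = (int)st.vx.size(), nf = (int)st.fa.size();
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) { V(i,0)=st.vx[i]; V(i,1)=st.vy[i]; V(i,2)=st.vz[i]; }
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nf; ++i) { F(i,0)=st.fa[i]+1; F(i,1)=st.fb[i]+1; F(i,2)=st.fc[i]+1; }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// [[Rcpp::export(name = ".vertex_components_cpp")]]
IntegerVector vertex_components_cpp(IntegerMatrix F, int nVerts) {
  std::vector<int> parent(nVerts);
  for (int i = 0; i < nVerts; ++i) parent[i] = i;
  struct UF {
    std::vector<int>& p;
    UF(std::vector<int>& p_) : p(p_) {}
    int find(int a) { while (p[a] != a) { p[a] = p[p[a]]; a = p[a]; } return a; }
    void unite(int a, int b) { a = find(a); b = find(b); if (a != b) p[a] = b; }
  } uf(parent);
  for (int f = 0; f < F.nrow(); ++f) {
    uf.unite(F(f,0)-1, F(f,1)-1);
    uf.unite(F(f,0)-1, F(f,2)-1);
  }
  IntegerVector out(nVerts);
  std::map<int,int> relabel;
  for (int i = 0; i < nVerts; ++i) {
    int r = uf.find(i);
    std::map<int,int>::iterator it = relabel.find(r);
    int lab;
    if (it == relabel.end()) { lab = (int)relabel.size() + 1; relabel[r] = lab; }
    else lab = it->second;
    out[i] = lab;
  }
  return out;
}
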