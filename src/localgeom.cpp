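// Per-point local geometry: covariance-eigen normals with surface-variation
// curvature, and moving-least-squares plane projection with Gaussian weights.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export(name = ".local_pca_cpp")]]
List local_pca_cpp(NumericMatrix P, IntegerMatrix nnIdx) {
  const int n = P.nrow(), k = nnIdx.ncol();
  NumericMatrix normals(n, 3);
  NumericVector curv(n);
  arma::mat C(3,3);
  arma::vec eval(3);
  arma::mat evec(3,3);
  for (int i = 0; i < n; ++i) {
    double mx = 0, my = 0, mz = 0;
    for (int j = 0; j < k; ++j) {
      int q = nnIdx(i,j) - 1;
      mx += P(q,0); my += P(q,1); mz += P(q,2);
    }
    mx /= k; my /= k; mz /= k;
    C.zeros();
    for (int j = 0; j < k; ++j) {
      int q = nnIdx(i,j) - 1;
      double dx = P(q,0)-mx, dy = P(q,1)-my, dz = P(q,2)-mz;
      C(0,0) += dx*dx; C(0,1) += dx*dy; C(0,2) += dx*dz;
      C(1,1) += dy*dy; C(1,2) += dy*dz; C(2,2) += dz*dz;
    }
    C(1,0) = C(0,1); C(2,0) = C(0,2); C(2,1) = C(1,2);
    double tr = C(0,0) + C(1,1) + C(2,2);
    if (tr <= 0) { // all neighbors coincide: arbitrary normal, zero curvature
      normals(i,0) = 0; normals(i,1) = 0; normals(i,2) = 1; curv[i] = 0;
      continue;
    }
    arma::eig_sym(eval, evec, C); // ascending eigenvalues
    normals(i,0) = evec(0,0); normals(i,1) = evec(1,0); normals(i,2) = evec(2,0);
    double cv = eval(0) / tr;
    curv[i] = cv < 0 ? 0 : cv;
  }
  return List::create(_["normals"] = normals, _["curvature"] = curv);
}

// [[Rcpp::export(name = ".mls_cpp")]]
List mls_cpp(NumericMatrix P, IntegerMatrix nnIdx, NumericMatrix nnDist,
             double radius, double h) {
  const int n = P.nrow(), k = nnIdx.ncol();
  NumericMatrix out(n, 3), nrm(n, 3);
  LogicalVector smoothed(n);
  arma::vec eval(3);
  arma::mat evec(3,3), C(3,3);
  const double h2 = h * h;
  for (int i = 0; i < n; ++i) {
    // neighbors within radius
    int m = 0;
    for (int j = 0; j < k; ++j) if (nnDist(i,j) <= radius) ++m; else break;
    if (m < 4) {
      out(i,0) = P(i,0); out(i,1) = P(i,1); out(i,2) = P(i,2);
      nrm(i,0) = NA_REAL; nrm(i,1) = NA_REAL; nrm(i,2) = NA_REAL;
      smoothed[i] = false;
      continue;
    }
    double qx = P(i,0), qy = P(i,1), qz = P(i,2);
    double nx = 0, ny = 0, nz = 1, D = 0;
    for (int pass = 0; pass < 2; ++pass) {
      double sw = 0, cx = 0, cy = 0, cz = 0;
      C.zeros();
      for (int j = 0; j < m; ++j) {
        int q = nnIdx(i,j) - 1;
        double dx = P(q,0)-qx, dy = P(q,1)-qy, dz = P(q,2)-qz;
        double w = std::exp(-(dx*dx + dy*dy + dz*dz) / h2);
        sw += w;
        cx += w*P(q,0); cy += w*P(q,1); cz += w*P(q,2);
      }
      cx /= sw; cy /= sw; cz /= sw;
      for (int j = 0; j < m; ++j) {
        int q = nnIdx(i,j) - 1;
        double dxq = P(q,0)-qx, dyq = P(q,1)-qy, dzq = P(q,2)-qz;
        double w = std::exp(-(dxq*dxq + dyq*dyq + dzq*dzq) / h2);
        double dx = P(q,0)-cx, dy = P(q,1)-cy, dz = P(q,2)-cz;
        C(0,0) += w*dx*dx; C(0,1) += w*dx*dy; C(0,2) += w*dx*dz;
        C(1,1) += w*dy*dy; C(1,2) += w*dy*dz; C(2,2) += w*dz*dz;
      }
      C(1,0) = C(0,1); C(2,0) = C(0,2); C(2,1) = C(1,2);
      arma::eig_sym(eval, evec, C);
      nx = evec(0,0); ny = evec(1,0); nz = evec(2,0);
      D = nx*cx + ny*cy + nz*cz;
      // recentre weights on the projection of p onto the fitted plane
      double t = nx*P(i,0) + ny*P(i,1) + nz*P(i,2) - D;
      qx = P(i,0) - t*nx; qy = P(i,1) - t*ny; qz = P(i,2) - t*nz;
    }
    out(i,0) = qx; out(i,1) = qy; out(i,2) = qz;
    nrm(i,0) = nx; nrm(i,1) = ny; nrm(i,2) = nz;
    smoothed[i] = true;
  }
  return List::create(_["points"] = out, _["normals"] = nrm, _["smoothed"] = smoothed);
}
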