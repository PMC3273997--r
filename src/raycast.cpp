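// Virtual-scanner ray casting.
//
// Beams leave the station origin on a regular (zenith x azimuth) angular
// grid, as from a galvano/stepper scanner head. For each beam the nearest
// ray-triangle intersection (Moller-Trumbore, first hit) is kept, which
// gives occlusion for free. Rather than testing every beam against every
// triangle, each triangle is rasterized onto the angular grid: only beams
// whose indices fall inside the triangle's angular bounding box are tested.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Moller-Trumbore; origin at 0, inclusive edges. Returns t > tmin or -1.
static inline double mt_hit(double dx, double dy, double dz,
                            const double *a, const double *b,
                            const double *c, double tmin) {
  double e1x = b[0] - a[0], e1y = b[1] - a[1], e1z = b[2] - a[2];
  double e2x = c[0] - a[0], e2y = c[1] - a[1], e2z = c[2] - a[2];
  double px = dy * e2z - dz * e2y;
  double py = dz * e2x - dx * e2z;
  double pz = dx * e2y - dy * e2x;
  double det = e1x * px + e1y * py + e1z * pz;
  double scale = std::sqrt((e1x * e1x + e1y * e1y + e1z * e1z) *
                           (e2x * e2x + e2y * e2y + e2z * e2z));
  if (std::fabs(det) < 1e-14 * std::max(scale, 1e-300)) return -1.0;
  double inv = 1.0 / det;
  double tx = -a[0], ty = -a[1], tz = -a[2];
  double u = (tx * px + ty * py + tz * pz) * inv;
  if (u < -1e-12 || u > 1.0 + 1e-12) return -1.0;
  double qx = ty * e1z - tz * e1y;
  double qy = tz * e1x - tx * e1z;
  double qz = tx * e1y - ty * e1x;
  double v = (dx * qx + dy * qy + dz * qz) * inv;
  if (v < -1e-12 || u + v > 1.0 + 1e-12) return -1.0;
  double t = (e2x * qx + e2y * qy + e2z * qz) * inv;
  if (t <= tmin) return -1.0;
  return t;
}

// [[Rcpp::export]]
List scan_grid_cpp(NumericMatrix V, IntegerMatrix F, IntegerVector leaf,
                   double theta0, double dtheta, int ntheta,
                   double phi0, double dphi, int nphi) {
  const int nf = F.nrow();
  const long nb = (long)ntheta * nphi;
  std::vector<double> tbest(nb, -1.0);
  std::vector<int> lbest(nb, 0);

  // precompute per-beam direction components
  std::vector<double> st(ntheta), ct(ntheta), cp(nphi), sp(nphi);
  for (int i = 0; i < ntheta; ++i) {
    double th = theta0 + i * dtheta;
    st[i] = std::sin(th);
    ct[i] = std::cos(th);
  }
  for (int j = 0; j < nphi; ++j) {
    double ph = phi0 + j * dphi;
    cp[j] = std::cos(ph);
    sp[j] = std::sin(ph);
  }

  double va[3], vb[3], vc[3];
  for (int f = 0; f < nf; ++f) {
    int ia = F(f, 0) - 1, ib = F(f, 1) - 1, ic = F(f, 2) - 1;
    double thmin = 1e30, thmax = -1e30, phmin = 1e30, phmax = -1e30;
    bool ok = true;
    for (int k = 0; k < 3; ++k) {
      int iv = (k == 0) ? ia : (k == 1 ? ib : ic);
      double X = V(iv, 0), Y = V(iv, 1), Z = V(iv, 2);
      double r = std::sqrt(X * X + Y * Y + Z * Z);
      if (r < 1e-9) { ok = false; break; }
      double th = std::acos(std::min(1.0, std::max(-1.0, Z / r)));
      double ph = std::atan2(Y, X);
      thmin = std::min(thmin, th); thmax = std::max(thmax, th);
      phmin = std::min(phmin, ph); phmax = std::max(phmax, ph);
      if (k == 0) { va[0] = X; va[1] = Y; va[2] = Z; }
      else if (k == 1) { vb[0] = X; vb[1] = Y; vb[2] = Z; }
      else { vc[0] = X; vc[1] = Y; vc[2] = Z; }
    }
    // The angular bounding box of the vertices covers the triangle only
    // when it spans neither the zenith/nadir axis nor the phi = +/-pi
    // seam -- always true for side-looking scan geometries like this
    // scanner's. Triangles that would wrap are skipped.
    if (!ok || phmax - phmin > 3.141592653589793) continue;
    int i0 = std::max(0, (int)std::floor((thmin - theta0) / dtheta) - 1);
    int i1 = std::min(ntheta - 1, (int)std::ceil((thmax - theta0) / dtheta) + 1);
    int j0 = std::max(0, (int)std::floor((phmin - phi0) / dphi) - 1);
    int j1 = std::min(nphi - 1, (int)std::ceil((phmax - phi0) / dphi) + 1);
    for (int i = i0; i <= i1; ++i) {
      for (int j = j0; j <= j1; ++j) {
        double dx = cp[j] * st[i], dy = sp[j] * st[i], dz = ct[i];
        double t = mt_hit(dx, dy, dz, va, vb, vc, 1e-9);
        if (t > 0) {
          long b = (long)i * nphi + j;
          if (tbest[b] < 0 || t < tbest[b]) {
            tbest[b] = t;
            lbest[b] = leaf[f];
          }
        }
      }
    }
  }

  long nhit = 0;
  for (long b = 0; b < nb; ++b) if (tbest[b] > 0) ++nhit;
  NumericMatrix hits(nhit, 4);  // t, dirx, diry, dirz
  IntegerVector hlab(nhit);
  long r = 0;
  for (int i = 0; i < ntheta; ++i) {
    for (int j = 0; j < nphi; ++j) {
      long b = (long)i * nphi + j;
      if (tbest[b] > 0) {
        hits(r, 0) = tbest[b];
        hits(r, 1) = cp[j] * st[i];
        hits(r, 2) = sp[j] * st[i];
        hits(r, 3) = ct[i];
        hlab[r] = lbest[b];
        ++r;
      }
    }
  }
  return List::create(_["hits"] = hits, _["label"] = hlab);
}

// [[Rcpp::export]]
double ray_triangle_cpp(NumericVector origin, NumericVector dir,
                        NumericMatrix tri) {
  double a[3], b[3], c[3];
  for (int k = 0; k < 3; ++k) {
    a[k] = tri(0, k) - origin[k];
    b[k] = tri(1, k) - origin[k];
    c[k] = tri(2, k) - origin[k];
  }
  double n2 = dir[0] * dir[0] + dir[1] * dir[1] + dir[2] * dir[2];
  if (n2 <= 0) stop("ray_triangle: zero direction");
  double nrm = std::sqrt(n2);
  double t = mt_hit(dir[0] / nrm, dir[1] / nrm, dir[2] / nrm, a, b, c, 1e-12);
  return t;  // -1 on miss; distance in meters otherwise
}

// Gaussian-elimination solve of a symmetric positive system (tiny m).
// Returns false when the pivot collapses (rank-deficient neighborhood).
static bool solve_sym(double A[6][6], double b[6], int m, double rtol) {
  double diag0 = 0;
  for (int i = 0; i < m; ++i) diag0 = std::max(diag0, std::fabs(A[i][i]));
  for (int col = 0; col < m; ++col) {
    int piv = col;
    for (int r = col + 1; r < m; ++r)
      if (std::fabs(A[r][col]) > std::fabs(A[piv][col])) piv = r;
    if (std::fabs(A[piv][col]) < rtol * diag0) return false;
    if (piv != col) {
      for (int c = 0; c < m; ++c) std::swap(A[piv][c], A[col][c]);
      std::swap(b[piv], b[col]);
    }
    for (int r = col + 1; r < m; ++r) {
      double f = A[r][col] / A[col][col];
      for (int c = col; c < m; ++c) A[r][c] -= f * A[col][c];
      b[r] -= f * b[col];
    }
  }
  for (int r = m - 1; r >= 0; --r) {
    for (int c = r + 1; c < m; ++c) b[r] -= A[r][c] * b[c];
    b[r] /= A[r][r];
  }
  return true;
}

// Weighted moving-least-squares smoothing of a height field w(u, v):
// each height is replaced by the value at (u_i, v_i) of a Gaussian-weighted
// polynomial fit (degree 1 or 2) over its radius neighbors. Exact on
// fields that are themselves polynomial of the fitted degree; degree 2
// preserves curvature, so larger radii denoise without flattening bends.
// [[Rcpp::export]]
NumericVector smooth_heights_cpp(NumericVector u, NumericVector v,
                                 NumericVector w, IntegerMatrix nn_idx,
                                 double sigma, int degree = 2) {
  const int n = u.size(), k = nn_idx.ncol();
  const int nterm = (degree >= 2) ? 6 : 3;  // 1, du, dv [, du2, dudv, dv2]
  NumericVector out(n);
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  double X[6], A[6][6], b[6], A1[6][6], b1[6];
  for (int i = 0; i < n; ++i) {
    for (int r = 0; r < 6; ++r) {
      b[r] = 0;
      for (int c = 0; c < 6; ++c) A[r][c] = 0;
    }
    int m = 0;
    double swt = 0, swv = 0;
    for (int jj = 0; jj < k; ++jj) {
      int j = nn_idx(i, jj);
      if (j == 0) break;  // 0-padded
      --j;
      double du = (u[j] - u[i]) / sigma, dv = (v[j] - v[i]) / sigma;
      double wt = std::exp(-(du * du + dv * dv) * sigma * sigma * inv2s2);
      X[0] = 1; X[1] = du; X[2] = dv;
      X[3] = du * du; X[4] = du * dv; X[5] = dv * dv;
      for (int r = 0; r < nterm; ++r) {
        for (int c = r; c < nterm; ++c) A[r][c] += wt * X[r] * X[c];
        b[r] += wt * X[r] * w[j];
      }
      swt += wt;
      swv += wt * w[j];
      ++m;
    }
    for (int r = 0; r < 6; ++r)
      for (int c = 0; c < r; ++c) A[r][c] = A[c][r];
    bool done = false;
    if (m >= nterm + 1) {
      for (int r = 0; r < 6; ++r) {
        b1[r] = b[r];
        for (int c = 0; c < 6; ++c) A1[r][c] = A[r][c];
      }
      if (solve_sym(A1, b1, nterm, 1e-8)) {
        out[i] = b1[0];
        done = true;
      }
    }
    if (!done && m >= 4) {  // fall back to the linear fit
      for (int r = 0; r < 6; ++r) {
        b1[r] = b[r];
        for (int c = 0; c < 6; ++c) A1[r][c] = A[r][c];
      }
      if (solve_sym(A1, b1, 3, 1e-8)) {
        out[i] = b1[0];
        done = true;
      }
    }
    if (!done) out[i] = (swt > 0) ? swv / swt : w[i];  // weighted mean
  }
  return out;
}
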