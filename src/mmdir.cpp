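#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

// Cubic (order-3) uniform B-spline kernel and its derivative, support (-2, 2).
static inline double bspl3(double t) {
  double a = std::fabs(t);
  if (a < 1.0) return (4.0 - 6.0 * a * a + 3.0 * a * a * a) / 6.0;
  if (a < 2.0) { double u = 2.0 - a; return u * u * u / 6.0; }
  return 0.0;
}

static inline double bspl3_deriv(double t) {
  double a = std::fabs(t), s = (t < 0.0) ? -1.0 : 1.0;
  if (a < 1.0) return s * (-2.0 * a + 1.5 * a * a);
  if (a < 2.0) { double u = 2.0 - a; return s * (-0.5 * u * u); }
  return 0.0;
}

// Displacement of a cubic B-spline free-form deformation at world points.
// Coefficients outside the control grid are treated as zero, so the field
// decays smoothly to the identity beyond the grid support.
// coef is an (n1*n2*n3*3) vector in R array order [i, j, k, component].
// [[Rcpp::export(name = ".cpp_bspline_disp")]]
NumericMatrix cpp_bspline_disp(NumericMatrix pts, NumericVector g0,
                               NumericVector gs, IntegerVector dims,
                               NumericVector coef) {
  const int n = pts.nrow();
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const int plane = n1 * n2, grid = plane * n3;
  NumericMatrix out(n, 3);
  const double *px = &pts(0, 0), *py = &pts(0, 1), *pz = &pts(0, 2);
  const double *cf = coef.begin();
  double *ox = &out(0, 0), *oy = &out(0, 1), *oz = &out(0, 2);
  double wx[4], wy[4], wz[4];
  for (int p = 0; p < n; ++p) {
    double u0 = (px[p] - g0[0]) / gs[0];
    double u1 = (py[p] - g0[1]) / gs[1];
    double u2 = (pz[p] - g0[2]) / gs[2];
    int i0 = (int)std::floor(u0), j0 = (int)std::floor(u1),
        k0 = (int)std::floor(u2);
    for (int d = 0; d < 4; ++d) {
      wx[d] = bspl3(u0 - (i0 + d - 1));
      wy[d] = bspl3(u1 - (j0 + d - 1));
      wz[d] = bspl3(u2 - (k0 + d - 1));
    }
    double dx = 0.0, dy = 0.0, dz = 0.0;
    for (int dk = 0; dk < 4; ++dk) {
      int k = k0 + dk - 1;
      if (k < 0 || k >= n3 || wz[dk] == 0.0) continue;
      for (int dj = 0; dj < 4; ++dj) {
        int j = j0 + dj - 1;
        if (j < 0 || j >= n2) continue;
        double wjk = wz[dk] * wy[dj];
        if (wjk == 0.0) continue;
        int base = n1 * (j + n2 * k);
        int ilo = (i0 - 1 < 0) ? 0 : i0 - 1;
        int ihi = (i0 + 2 >= n1) ? n1 - 1 : i0 + 2;
        for (int i = ilo; i <= ihi; ++i) {
          double w = wjk * wx[i - i0 + 1];
          int idx = i + base;
          dx += w * cf[idx];
          dy += w * cf[idx + grid];
          dz += w * cf[idx + 2 * grid];
        }
      }
    }
    ox[p] = dx; oy[p] = dy; oz[p] = dz;
  }
  return out;
}

// Chain rule accumulator: given dCost/dT(x) per point (N x 3), scatter-add
// through the B-spline weights to get dCost/dmu (n1*n2*n3*3).
// [[Rcpp::export(name = ".cpp_bspline_grad_accum")]]
NumericVector cpp_bspline_grad_accum(NumericMatrix pts, NumericVector g0,
                                     NumericVector gs, IntegerVector dims,
                                     NumericMatrix dcdpos) {
  const int n = pts.nrow();
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const int grid = n1 * n2 * n3;
  NumericVector out(3 * grid);
  const double *px = &pts(0, 0), *py = &pts(0, 1), *pz = &pts(0, 2);
  const double *d0 = &dcdpos(0, 0), *d1 = &dcdpos(0, 1),
               *d2 = &dcdpos(0, 2);
  double *o = out.begin();
  double wx[4], wy[4], wz[4];
  for (int p = 0; p < n; ++p) {
    double g0p = d0[p], g1p = d1[p], g2p = d2[p];
    if (g0p == 0.0 && g1p == 0.0 && g2p == 0.0) continue;
    double u0 = (px[p] - g0[0]) / gs[0];
    double u1 = (py[p] - g0[1]) / gs[1];
    double u2 = (pz[p] - g0[2]) / gs[2];
    int i0 = (int)std::floor(u0), j0 = (int)std::floor(u1),
        k0 = (int)std::floor(u2);
    for (int d = 0; d < 4; ++d) {
      wx[d] = bspl3(u0 - (i0 + d - 1));
      wy[d] = bspl3(u1 - (j0 + d - 1));
      wz[d] = bspl3(u2 - (k0 + d - 1));
    }
    for (int dk = 0; dk < 4; ++dk) {
      int k = k0 + dk - 1;
      if (k < 0 || k >= n3 || wz[dk] == 0.0) continue;
      for (int dj = 0; dj < 4; ++dj) {
        int j = j0 + dj - 1;
        if (j < 0 || j >= n2) continue;
        double wjk = wz[dk] * wy[dj];
        if (wjk == 0.0) continue;
        int base = n1 * (j + n2 * k);
        int ilo = (i0 - 1 < 0) ? 0 : i0 - 1;
        int ihi = (i0 + 2 >= n1) ? n1 - 1 : i0 + 2;
        for (int i = ilo; i <= ihi; ++i) {
          double w = wjk * wx[i - i0 + 1];
          int idx = i + base;
          o[idx] += w * g0p;
          o[idx + grid] += w * g1p;
          o[idx + 2 * grid] += w * g2p;
        }
      }
    }
  }
  return out;
}

// Trilinear interpolation of a 3D scalar array at world points, with an
// optional spatial gradient (per mm). Points outside the grid get `fill`
// and a zero gradient; `inside` flags them.
// [[Rcpp::export(name = ".cpp_trilinear")]]
List cpp_trilinear(NumericVector arr, IntegerVector dims,
                   NumericVector spacing, NumericVector origin,
                   NumericMatrix pts, bool want_grad, double fill) {
  const int n = pts.nrow();
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  NumericVector val(n);
  LogicalVector inside(n);
  NumericMatrix grad = want_grad ? NumericMatrix(n, 3) : NumericMatrix(0, 0);
  const double tol = 1e-9;   // voxel units; absorbs round-trip rounding
  for (int p = 0; p < n; ++p) {
    double v0 = (pts(p, 0) - origin[0]) / spacing[0];
    double v1 = (pts(p, 1) - origin[1]) / spacing[1];
    double v2 = (pts(p, 2) - origin[2]) / spacing[2];
    if (v0 < -tol || v1 < -tol || v2 < -tol ||
        v0 > n1 - 1.0 + tol || v1 > n2 - 1.0 + tol ||
        v2 > n3 - 1.0 + tol) {
      val[p] = fill; inside[p] = false;
      continue;
    }
    inside[p] = true;
    if (v0 < 0.0) v0 = 0.0; else if (v0 > n1 - 1.0) v0 = n1 - 1.0;
    if (v1 < 0.0) v1 = 0.0; else if (v1 > n2 - 1.0) v1 = n2 - 1.0;
    if (v2 < 0.0) v2 = 0.0; else if (v2 > n3 - 1.0) v2 = n3 - 1.0;
    int i0 = (int)std::floor(v0), j0 = (int)std::floor(v1),
        k0 = (int)std::floor(v2);
    if (i0 > n1 - 2) i0 = n1 - 2;
    if (j0 > n2 - 2) j0 = n2 - 2;
    if (k0 > n3 - 2) k0 = n3 - 2;
    if (n1 == 1) i0 = 0;
    if (n2 == 1) j0 = 0;
    if (n3 == 1) k0 = 0;
    double fx = v0 - i0, fy = v1 - j0, fz = v2 - k0;
    int i1 = (n1 == 1) ? i0 : i0 + 1;
    int j1 = (n2 == 1) ? j0 : j0 + 1;
    int k1 = (n3 == 1) ? k0 : k0 + 1;
    double c000 = arr[i0 + n1 * (j0 + n2 * k0)];
    double c100 = arr[i1 + n1 * (j0 + n2 * k0)];
    double c010 = arr[i0 + n1 * (j1 + n2 * k0)];
    double c110 = arr[i1 + n1 * (j1 + n2 * k0)];
    double c001 = arr[i0 + n1 * (j0 + n2 * k1)];
    double c101 = arr[i1 + n1 * (j0 + n2 * k1)];
    double c011 = arr[i0 + n1 * (j1 + n2 * k1)];
    double c111 = arr[i1 + n1 * (j1 + n2 * k1)];
    double c00 = c000 * (1 - fx) + c100 * fx;
    double c10 = c010 * (1 - fx) + c110 * fx;
    double c01 = c001 * (1 - fx) + c101 * fx;
    double c11 = c011 * (1 - fx) + c111 * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    val[p] = c0 * (1 - fz) + c1 * fz;
    if (want_grad) {
      double dX = ((c100 - c000) * (1 - fy) + (c110 - c010) * fy) * (1 - fz) +
                  ((c101 - c001) * (1 - fy) + (c111 - c011) * fy) * fz;
      double dY = (c10 - c00) * (1 - fz) + (c11 - c01) * fz;
      double dZ = c1 - c0;
      grad(p, 0) = dX / spacing[0];
      grad(p, 1) = dY / spacing[1];
      grad(p, 2) = dZ / spacing[2];
    }
  }
  return List::create(_["value"] = val, _["grad"] = grad,
                      _["inside"] = inside);
}

// One-dimensional squared-distance transform (Felzenszwalb & Huttenlocher),
// sample positions i * w.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 double w, int n) {
  static thread_local std::vector<int> v;
  static thread_local std::vector<double> z;
  v.assign(n, 0); z.assign(n + 1, 0.0);
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0; z[0] = -INF; z[1] = INF;
  const double w2 = w * w;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    double s;
    while (true) {
      int p = v[k];
      if (f[p] == INF) { // first finite sample
        if (k == 0) { v[0] = q; z[0] = -INF; z[1] = INF; s = -INF; break; }
        --k; continue;
      }
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (s <= z[k]) { --k; continue; }
      break;
    }
    if (s == -INF) continue;
    ++k; v[k] = q; z[k] = s; z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    int p = v[k];
    d[q] = (f[p] == INF) ? INF : w2 * (q - p) * (q - p) + f[p];
  }
}

// Exact squared Euclidean distance transform (mm^2) to the nearest
// foreground voxel center, with anisotropic spacing.
// [[Rcpp::export(name = ".cpp_edt_sq")]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dims,
                         NumericVector spacing) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const int nt = n1 * n2 * n3;
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector D(nt);
  for (int i = 0; i < nt; ++i) D[i] = mask[i] ? 0.0 : INF;
  std::vector<double> f, d;
  // axis 1 (stride 1)
  f.resize(n1); d.resize(n1);
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j) {
      int base = n1 * (j + n2 * k);
      for (int i = 0; i < n1; ++i) f[i] = D[base + i];
      dt1d(f, d, spacing[0], n1);
      for (int i = 0; i < n1; ++i) D[base + i] = d[i];
    }
  // axis 2 (stride n1)
  f.resize(n2); d.resize(n2);
  for (int k = 0; k < n3; ++k)
    for (int i = 0; i < n1; ++i) {
      int base = i + n1 * n2 * k;
      for (int j = 0; j < n2; ++j) f[j] = D[base + n1 * j];
      dt1d(f, d, spacing[1], n2);
      for (int j = 0; j < n2; ++j) D[base + n1 * j] = d[j];
    }
  // axis 3 (stride n1*n2)
  f.resize(n3); d.resize(n3);
  const int plane = n1 * n2;
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      int base = i + n1 * j;
      for (int k = 0; k < n3; ++k) f[k] = D[base + plane * k];
      dt1d(f, d, spacing[2], n3);
      for (int k = 0; k < n3; ++k) D[base + plane * k] = d[k];
    }
  return D;
}

// Connected-component labelling (26-connectivity) of a binary volume.
// Labels are 1-based in decreasing order of discovery (relabelled by size
// on the R side when needed).
// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const int nt = n1 * n2 * n3;
  IntegerVector lab(nt, 0);
  std::vector<int> stack;
  int next = 0;
  for (int s = 0; s < nt; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int i = cur % n1, j = (cur / n1) % n2, k = cur / (n1 * n2);
      for (int dk = -1; dk <= 1; ++dk) {
        int kk = k + dk; if (kk < 0 || kk >= n3) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          int jj = j + dj; if (jj < 0 || jj >= n2) continue;
          for (int di = -1; di <= 1; ++di) {
            int ii = i + di; if (ii < 0 || ii >= n1) continue;
            int idx = ii + n1 * (jj + n2 * kk);
            if (mask[idx] && lab[idx] == 0) {
              lab[idx] = next;
              stack.push_back(idx);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Kernel weight helpers exposed for the Parzen mutual-information estimator.
// [[Rcpp::export(name = ".cpp_bspl3")]]
NumericVector cpp_bspl3(NumericVector t) {
  NumericVector out(t.size());
  for (R_xlen_t i = 0; i < t.size(); ++i) out[i] = bspl3(t[i]);
  return out;
}

// [[Rcpp::export(name = ".cpp_bspl3_deriv")]]
NumericVector cpp_bspl3_deriv(NumericVector t) {
  NumericVector out(t.size());
  for (R_xlen_t i = 0; i < t.size(); ++i) out[i] = bspl3_deriv(t[i]);
  return out;
}
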