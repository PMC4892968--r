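#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Column-major flat index helpers (0-based), matching R array layout.
static inline R_xlen_t idx3(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

// Sample a 3D volume at arbitrary world points. Continuous voxel index
// c = (x - origin) / spacing; points outside [-0.5, n-0.5] get `bg`,
// in-domain points are clamped to the voxel-center lattice before
// interpolation (half-voxel border behaves as edge replication).
// [[Rcpp::export]]
NumericVector cpp_sample3(NumericVector arr, IntegerVector dim,
                          NumericVector spacing, NumericVector origin,
                          NumericMatrix pts, bool linear, double bg) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = pts.nrow();
  NumericVector out(n);
  for (R_xlen_t p = 0; p < n; ++p) {
    double cx = (pts(p, 0) - origin[0]) / spacing[0];
    double cy = (pts(p, 1) - origin[1]) / spacing[1];
    double cz = (pts(p, 2) - origin[2]) / spacing[2];
    if (!R_finite(cx) || !R_finite(cy) || !R_finite(cz) ||
        cx < -0.5 || cy < -0.5 || cz < -0.5 ||
        cx > nx - 0.5 || cy > ny - 0.5 || cz > nz - 0.5) {
      out[p] = bg;
      continue;
    }
    cx = std::min(std::max(cx, 0.0), (double)(nx - 1));
    cy = std::min(std::max(cy, 0.0), (double)(ny - 1));
    cz = std::min(std::max(cz, 0.0), (double)(nz - 1));
    if (!linear) {
      int i = (int)std::floor(cx + 0.5), j = (int)std::floor(cy + 0.5),
          k = (int)std::floor(cz + 0.5);
      out[p] = arr[idx3(i, j, k, nx, ny)];
    } else {
      int i0 = (int)std::floor(cx), j0 = (int)std::floor(cy), k0 = (int)std::floor(cz);
      int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1),
          k1 = std::min(k0 + 1, nz - 1);
      double fx = cx - i0, fy = cy - j0, fz = cz - k0;
      double v000 = arr[idx3(i0, j0, k0, nx, ny)], v100 = arr[idx3(i1, j0, k0, nx, ny)];
      double v010 = arr[idx3(i0, j1, k0, nx, ny)], v110 = arr[idx3(i1, j1, k0, nx, ny)];
      double v001 = arr[idx3(i0, j0, k1, nx, ny)], v101 = arr[idx3(i1, j0, k1, nx, ny)];
      double v011 = arr[idx3(i0, j1, k1, nx, ny)], v111 = arr[idx3(i1, j1, k1, nx, ny)];
      double v00 = v000 + fx * (v100 - v000), v10 = v010 + fx * (v110 - v010);
      double v01 = v001 + fx * (v101 - v001), v11 = v011 + fx * (v111 - v011);
      double v0 = v00 + fy * (v10 - v00), v1 = v01 + fy * (v11 - v01);
      out[p] = v0 + fz * (v1 - v0);
    }
  }
  return out;
}

// 2D analogue of cpp_sample3.
// [[Rcpp::export]]
NumericVector cpp_sample2(NumericVector arr, IntegerVector dim,
                          NumericVector spacing, NumericVector origin,
                          NumericMatrix pts, bool linear, double bg) {
  const int nx = dim[0], ny = dim[1];
  const R_xlen_t n = pts.nrow();
  NumericVector out(n);
  for (R_xlen_t p = 0; p < n; ++p) {
    double cx = (pts(p, 0) - origin[0]) / spacing[0];
    double cy = (pts(p, 1) - origin[1]) / spacing[1];
    if (!R_finite(cx) || !R_finite(cy) ||
        cx < -0.5 || cy < -0.5 || cx > nx - 0.5 || cy > ny - 0.5) {
      out[p] = bg;
      continue;
    }
    cx = std::min(std::max(cx, 0.0), (double)(nx - 1));
    cy = std::min(std::max(cy, 0.0), (double)(ny - 1));
    if (!linear) {
      int i = (int)std::floor(cx + 0.5), j = (int)std::floor(cy + 0.5);
      out[p] = arr[(R_xlen_t)i + (R_xlen_t)nx * j];
    } else {
      int i0 = (int)std::floor(cx), j0 = (int)std::floor(cy);
      int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1);
      double fx = cx - i0, fy = cy - j0;
      double v00 = arr[(R_xlen_t)i0 + (R_xlen_t)nx * j0];
      double v10 = arr[(R_xlen_t)i1 + (R_xlen_t)nx * j0];
      double v01 = arr[(R_xlen_t)i0 + (R_xlen_t)nx * j1];
      double v11 = arr[(R_xlen_t)i1 + (R_xlen_t)nx * j1];
      double v0 = v00 + fx * (v10 - v00), v1 = v01 + fx * (v11 - v01);
      out[p] = v0 + fy * (v1 - v0);
    }
  }
  return out;
}

static void gauss_kernel(double sigma, std::vector<double> &w) {
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  if (sigma <= 0) { w.assign(1, 1.0); return; }
  w.assign(2 * r + 1, 0.0);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    w[i + r] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += w[i + r];
  }
  for (double &x : w) x /= s;
}

// Separable Gaussian smoothing along one axis with reflective boundaries.
static void smooth_axis3(std::vector<double> &a, int nx, int ny, int nz,
                         int axis, double sigma) {
  if (sigma <= 0) return;
  std::vector<double> w;
  gauss_kernel(sigma, w);
  int r = ((int)w.size() - 1) / 2;
  std::vector<double> tmp(a.size());
  int n[3] = {nx, ny, nz};
  int len = n[axis];
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int c[3] = {i, j, k};
        double acc = 0.0;
        for (int o = -r; o <= r; ++o) {
          int q = c[axis] + o;
          if (q < 0) q = -q - 1;           // reflect
          if (q >= len) q = 2 * len - q - 1;
          int cc[3] = {i, j, k};
          cc[axis] = q;
          acc += w[o + r] * a[idx3(cc[0], cc[1], cc[2], nx, ny)];
        }
        tmp[idx3(i, j, k, nx, ny)] = acc;
      }
  a.swap(tmp);
}

// [[Rcpp::export]]
NumericVector cpp_gauss3(NumericVector arr, IntegerVector dim, NumericVector sigma) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> a(arr.begin(), arr.end());
  for (int ax = 0; ax < 3; ++ax) smooth_axis3(a, nx, ny, nz, ax, sigma[ax]);
  return NumericVector(a.begin(), a.end());
}

// [[Rcpp::export]]
NumericVector cpp_gauss2(NumericVector arr, IntegerVector dim, NumericVector sigma) {
  int nx = dim[0], ny = dim[1];
  std::vector<double> a(arr.begin(), arr.end());
  for (int ax = 0; ax < 2; ++ax) smooth_axis3(a, nx, ny, 1, ax, sigma[ax]);
  return NumericVector(a.begin(), a.end());
}

// Windowed sums over (2r+1)^3 boxes clamped to the array domain, via a
// running-sum sweep per axis. Returned alongside window voxel counts.
static void box_axis3(std::vector<double> &a, int nx, int ny, int nz,
                      int axis, int r) {
  std::vector<double> tmp(a.size());
  int n[3] = {nx, ny, nz};
  int len = n[axis];
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int c[3] = {i, j, k};
        double acc = 0.0;
        int lo = std::max(0, c[axis] - r), hi = std::min(len - 1, c[axis] + r);
        for (int q = lo; q <= hi; ++q) {
          int cc[3] = {i, j, k};
          cc[axis] = q;
          acc += a[idx3(cc[0], cc[1], cc[2], nx, ny)];
        }
        tmp[idx3(i, j, k, nx, ny)] = acc;
      }
  a.swap(tmp);
}

// [[Rcpp::export]]
NumericVector cpp_box3(NumericVector arr, IntegerVector dim, int r) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> a(arr.begin(), arr.end());
  for (int ax = 0; ax < 3; ++ax) box_axis3(a, nx, ny, nz, ax, r);
  return NumericVector(a.begin(), a.end());
}

// Median filter over (2r+1)^3 windows clamped at the boundary.
// [[Rcpp::export]]
NumericVector cpp_median3(NumericVector arr, IntegerVector dim, int r) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(arr.size());
  std::vector<double> buf;
  buf.reserve((2 * r + 1) * (2 * r + 1) * (2 * r + 1));
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        buf.clear();
        for (int kk = std::max(0, k - r); kk <= std::min(nz - 1, k + r); ++kk)
          for (int jj = std::max(0, j - r); jj <= std::min(ny - 1, j + r); ++jj)
            for (int ii = std::max(0, i - r); ii <= std::min(nx - 1, i + r); ++ii)
              buf.push_back(arr[idx3(ii, jj, kk, nx, ny)]);
        size_t m = buf.size() / 2;
        std::nth_element(buf.begin(), buf.begin() + m, buf.end());
        double med = buf[m];
        if (buf.size() % 2 == 0) {
          std::nth_element(buf.begin(), buf.begin() + m - 1, buf.end());
          med = 0.5 * (med + buf[m - 1]);
        }
        out[idx3(i, j, k, nx, ny)] = med;
      }
  return out;
}

// Gauss-Seidel relaxation (SOR) of the Laplace equation on voxels where
// free_mask != 0; all other voxels hold fixed boundary values. Anisotropic
// spacing enters through 1/h^2 weights. Stops when the max update over a
// sweep falls below tol.
// [[Rcpp::export]]
List cpp_laplace(NumericVector phi0, IntegerVector dim, NumericVector spacing,
                 IntegerVector free_mask, int max_iter, double tol, double omega) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector phi = clone(phi0);
  double wx = 1.0 / (spacing[0] * spacing[0]);
  double wy = 1.0 / (spacing[1] * spacing[1]);
  double wz = 1.0 / (spacing[2] * spacing[2]);
  double denom = 2.0 * (wx + wy + wz);
  double resid = R_PosInf;
  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    resid = 0.0;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          R_xlen_t c = idx3(i, j, k, nx, ny);
          if (!free_mask[c]) continue;
          // Neumann (reflected) neighbors at the grid faces
          int im = i > 0 ? i - 1 : i + 1, ip = i < nx - 1 ? i + 1 : i - 1;
          int jm = j > 0 ? j - 1 : j + 1, jp = j < ny - 1 ? j + 1 : j - 1;
          int km = k > 0 ? k - 1 : k + 1, kp = k < nz - 1 ? k + 1 : k - 1;
          double v = (wx * (phi[idx3(im, j, k, nx, ny)] + phi[idx3(ip, j, k, nx, ny)]) +
                      wy * (phi[idx3(i, jm, k, nx, ny)] + phi[idx3(i, jp, k, nx, ny)]) +
                      wz * (phi[idx3(i, j, km, nx, ny)] + phi[idx3(i, j, kp, nx, ny)])) / denom;
          double upd = phi[c] + omega * (v - phi[c]);
          double d = std::fabs(upd - phi[c]);
          if (d > resid) resid = d;
          phi[c] = upd;
        }
    if (resid < tol) { ++it; break; }
  }
  return List::create(_["phi"] = phi, _["iterations"] = it, _["residual"] = resid);
}

static inline double samp3(const double *a, int nx, int ny, int nz,
                           double cx, double cy, double cz) {
  cx = std::min(std::max(cx, 0.0), (double)(nx - 1));
  cy = std::min(std::max(cy, 0.0), (double)(ny - 1));
  cz = std::min(std::max(cz, 0.0), (double)(nz - 1));
  int i0 = (int)std::floor(cx), j0 = (int)std::floor(cy), k0 = (int)std::floor(cz);
  int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1), k1 = std::min(k0 + 1, nz - 1);
  double fx = cx - i0, fy = cy - j0, fz = cz - k0;
  double v00 = a[idx3(i0, j0, k0, nx, ny)] + fx * (a[idx3(i1, j0, k0, nx, ny)] - a[idx3(i0, j0, k0, nx, ny)]);
  double v10 = a[idx3(i0, j1, k0, nx, ny)] + fx * (a[idx3(i1, j1, k0, nx, ny)] - a[idx3(i0, j1, k0, nx, ny)]);
  double v01 = a[idx3(i0, j0, k1, nx, ny)] + fx * (a[idx3(i1, j0, k1, nx, ny)] - a[idx3(i0, j0, k1, nx, ny)]);
  double v11 = a[idx3(i0, j1, k1, nx, ny)] + fx * (a[idx3(i1, j1, k1, nx, ny)] - a[idx3(i0, j1, k1, nx, ny)]);
  double v0 = v00 + fy * (v10 - v00), v1 = v01 + fy * (v11 - v01);
  return v0 + fz * (v1 - v0);
}

static inline bool in_cortex(const int *m, int nx, int ny, int nz,
                             double cx, double cy, double cz) {
  int i = (int)std::floor(cx + 0.5), j = (int)std::floor(cy + 0.5), k = (int)std::floor(cz + 0.5);
  if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return false;
  return m[idx3(i, j, k, nx, ny)] != 0;
}

// Integrate streamlines of the Laplace potential from seed points, in both
// directions (-grad phi toward the pial surface, +grad phi toward white
// matter). A streamline terminates when its nearest voxel leaves the cortex
// mask; the exit point is refined by bisection, placing the surface at the
// half-voxel interface. Returns per seed: length to pial (mm), length to WM
// (mm), and a success flag (both directions terminated).
// [[Rcpp::export]]
NumericMatrix cpp_streamlines(NumericVector phi, IntegerVector cortex,
                              IntegerVector dim, NumericVector spacing,
                              NumericVector origin, NumericMatrix seeds,
                              double step_vox, int max_steps) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const double *ph = phi.begin();
  const int *cm = cortex.begin();
  double hmin = std::min(spacing[0], std::min(spacing[1], spacing[2]));
  double step = step_vox * hmin;
  R_xlen_t n = seeds.nrow();
  NumericMatrix out(n, 3);
  for (R_xlen_t s = 0; s < n; ++s) {
    double lens[2] = {0.0, 0.0};
    bool ok = true;
    for (int dir = 0; dir < 2; ++dir) {
      double sign = dir == 0 ? -1.0 : 1.0;  // -grad: pial; +grad: WM
      double x = seeds(s, 0), y = seeds(s, 1), z = seeds(s, 2);
      double cx = (x - origin[0]) / spacing[0];
      double cy = (y - origin[1]) / spacing[1];
      double cz = (z - origin[2]) / spacing[2];
      if (!in_cortex(cm, nx, ny, nz, cx, cy, cz)) { ok = false; break; }
      double len = 0.0;
      int st;
      for (st = 0; st < max_steps; ++st) {
        // gradient of phi by central differences of trilinear samples (mm units)
        double gx = (samp3(ph, nx, ny, nz, cx + 0.5, cy, cz) -
                     samp3(ph, nx, ny, nz, cx - 0.5, cy, cz)) / spacing[0];
        double gy = (samp3(ph, nx, ny, nz, cx, cy + 0.5, cz) -
                     samp3(ph, nx, ny, nz, cx, cy - 0.5, cz)) / spacing[1];
        double gz = (samp3(ph, nx, ny, nz, cx, cy, cz + 0.5) -
                     samp3(ph, nx, ny, nz, cx, cy, cz - 0.5)) / spacing[2];
        double g = std::sqrt(gx * gx + gy * gy + gz * gz);
        if (g < 1e-12) { ok = false; break; }
        gx *= sign / g; gy *= sign / g; gz *= sign / g;
        // RK2 midpoint step in world units
        double mx = cx + 0.5 * step * gx / spacing[0];
        double my = cy + 0.5 * step * gy / spacing[1];
        double mz = cz + 0.5 * step * gz / spacing[2];
        double hx = (samp3(ph, nx, ny, nz, mx + 0.5, my, mz) -
                     samp3(ph, nx, ny, nz, mx - 0.5, my, mz)) / spacing[0];
        double hy = (samp3(ph, nx, ny, nz, mx, my + 0.5, mz) -
                     samp3(ph, nx, ny, nz, mx, my - 0.5, mz)) / spacing[1];
        double hz = (samp3(ph, nx, ny, nz, mx, my, mz + 0.5) -
                     samp3(ph, nx, ny, nz, mx, my, mz - 0.5)) / spacing[2];
        double h = std::sqrt(hx * hx + hy * hy + hz * hz);
        if (h < 1e-12) { ok = false; break; }
        hx *= sign / h; hy *= sign / h; hz *= sign / h;
        double nxc = cx + step * hx / spacing[0];
        double nyc = cy + step * hy / spacing[1];
        double nzc = cz + step * hz / spacing[2];
        if (!in_cortex(cm, nx, ny, nz, nxc, nyc, nzc)) {
          // bisect the exit fraction for sub-step surface placement
          double lo = 0.0, hi = 1.0;
          for (int b = 0; b < 6; ++b) {
            double mid = 0.5 * (lo + hi);
            if (in_cortex(cm, nx, ny, nz, cx + mid * (nxc - cx),
                          cy + mid * (nyc - cy), cz + mid * (nzc - cz)))
              lo = mid;
            else
              hi = mid;
          }
          len += step * 0.5 * (lo + hi);
          break;
        }
        cx = nxc; cy = nyc; cz = nzc;
        len += step;
      }
      if (st == max_steps) ok = false;
      lens[dir] = len;
      if (!ok) break;
    }
    out(s, 0) = lens[0];
    out(s, 1) = lens[1];
    out(s, 2) = ok ? 1.0 : 0.0;
  }
  return out;
}

// For each query point: nearest labeled center (Euclidean); exact ties go to
// the smaller label id. Returns label and distance.
// [[Rcpp::export]]
List cpp_nn_label(NumericMatrix pts, NumericMatrix centers, IntegerVector labels) {
  R_xlen_t n = pts.nrow(), m = centers.nrow();
  IntegerVector lab(n);
  NumericVector dist(n);
  for (R_xlen_t p = 0; p < n; ++p) {
    double best = R_PosInf;
    int bl = NA_INTEGER;
    for (R_xlen_t c = 0; c < m; ++c) {
      double dx = pts(p, 0) - centers(c, 0);
      double dy = pts(p, 1) - centers(c, 1);
      double dz = pts(p, 2) - centers(c, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best - 1e-24 || (std::fabs(d2 - best) <= 1e-24 && labels[c] < bl)) {
        best = d2;
        bl = labels[c];
      }
    }
    lab[p] = bl;
    dist[p] = std::sqrt(best);
  }
  return List::create(_["label"] = lab, _["distance"] = dist);
}

// Per-row minimum Euclidean distance from points in A to points in B.
// [[Rcpp::export]]
NumericVector cpp_nn_dist(NumericMatrix A, NumericMatrix B) {
  R_xlen_t n = A.nrow(), m = B.nrow(), d = A.ncol();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double best = R_PosInf;
    for (R_xlen_t j = 0; j < m; ++j) {
      double acc = 0.0;
      for (R_xlen_t c = 0; c < d; ++c) {
        double dd = A(i, c) - B(j, c);
        acc += dd * dd;
      }
      if (acc < best) best = acc;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
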