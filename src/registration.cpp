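// Low-level numerical kernels: trilinear sampling, separable Gaussian
// smoothing, diffeomorphic demons iterations, field inversion, Jacobian
// determinants, downsampling, exhaustive nearest-point search and
// 26-connected component labelling. All grids are column-major
// (R array layout), voxel indices 0-based, fields in voxel units unless
// stated otherwise.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Trilinear interpolation at 0-based voxel coordinates, with nearest-edge
// (clamped) extrapolation outside the grid.
static double sample3(const double* v, int nx, int ny, int nz,
                      double x, double y, double z) {
  x = clampd(x, 0.0, nx - 1.0);
  y = clampd(y, 0.0, ny - 1.0);
  z = clampd(z, 0.0, nz - 1.0);
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  x0 = clampi(x0, 0, nx - 1); y0 = clampi(y0, 0, ny - 1); z0 = clampi(z0, 0, nz - 1);
  int x1 = clampi(x0 + 1, 0, nx - 1);
  int y1 = clampi(y0 + 1, 0, ny - 1);
  int z1 = clampi(z0 + 1, 0, nz - 1);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  const size_t sx = 1, sy = (size_t)nx, sz = (size_t)nx * ny;
  #define V(i, j, k) v[(size_t)(i) * sx + (size_t)(j) * sy + (size_t)(k) * sz]
  double c00 = V(x0, y0, z0) * (1 - fx) + V(x1, y0, z0) * fx;
  double c10 = V(x0, y1, z0) * (1 - fx) + V(x1, y1, z0) * fx;
  double c01 = V(x0, y0, z1) * (1 - fx) + V(x1, y0, z1) * fx;
  double c11 = V(x0, y1, z1) * (1 - fx) + V(x1, y1, z1) * fx;
  #undef V
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// In-place separable Gaussian smoothing of one scalar volume.
static void gauss_axis(std::vector<double>& a, std::vector<double>& tmp,
                       int nx, int ny, int nz, const std::vector<double>& ker,
                       int axis) {
  const int r = (int)ker.size() / 2;
  const size_t sx = 1, sy = (size_t)nx, sz = (size_t)nx * ny;
  size_t stride = axis == 0 ? sx : (axis == 1 ? sy : sz);
  int n = axis == 0 ? nx : (axis == 1 ? ny : nz);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t idx = i * sx + j * sy + k * sz;
        int pos = axis == 0 ? i : (axis == 1 ? j : k);
        double acc = 0.0;
        for (int t = -r; t <= r; ++t) {
          int p = clampi(pos + t, 0, n - 1);
          acc += ker[t + r] * a[idx + (size_t)(p - pos) * stride];
        }
        tmp[idx] = acc;
      }
  a.swap(tmp);
}

static std::vector<double> gauss_kernel(double sigma) {
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int t = -r; t <= r; ++t) {
    k[t + r] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += k[t + r];
  }
  for (auto& v : k) v /= s;
  return k;
}

static void smooth_volume(std::vector<double>& a, int nx, int ny, int nz,
                          double sigma) {
  if (sigma <= 0) return;
  std::vector<double> tmp(a.size());
  std::vector<double> ker = gauss_kernel(sigma);
  for (int ax = 0; ax < 3; ++ax) gauss_axis(a, tmp, nx, ny, nz, ker, ax);
}

// Edge-aware (conductance-weighted) diffusion of one scalar component.
// cond holds a per-voxel conductance in [0, 1] (low across intensity
// boundaries); each pass applies s += lam * sum_faces c_face * (nbr - s)
// with face conductance = min of the two voxel conductances. lam <= 1/6
// guarantees stability.
static void aniso_pass(std::vector<double>& a, std::vector<double>& tmp,
                       const double* cond, int nx, int ny, int nz,
                       double lam) {
  const size_t SX = 1, SY = (size_t)nx, SZ = (size_t)nx * ny;
  size_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        double acc = 0.0;
        double c0 = cond[idx];
        if (i > 0)      { double c = std::min(c0, cond[idx - SX]); acc += c * (a[idx - SX] - a[idx]); }
        if (i < nx - 1) { double c = std::min(c0, cond[idx + SX]); acc += c * (a[idx + SX] - a[idx]); }
        if (j > 0)      { double c = std::min(c0, cond[idx - SY]); acc += c * (a[idx - SY] - a[idx]); }
        if (j < ny - 1) { double c = std::min(c0, cond[idx + SY]); acc += c * (a[idx + SY] - a[idx]); }
        if (k > 0)      { double c = std::min(c0, cond[idx - SZ]); acc += c * (a[idx - SZ] - a[idx]); }
        if (k < nz - 1) { double c = std::min(c0, cond[idx + SZ]); acc += c * (a[idx + SZ] - a[idx]); }
        tmp[idx] = a[idx] + lam * acc;
      }
  a.swap(tmp);
}

static void aniso_smooth(std::vector<double>& a, int nx, int ny, int nz,
                         const double* cond, int passes, double lam = 1.0 / 6.0) {
  std::vector<double> tmp(a.size());
  for (int p = 0; p < passes; ++p)
    aniso_pass(a, tmp, cond, nx, ny, nz, lam);
}

// [[Rcpp::export]]
NumericVector cpp_gaussian_smooth(NumericVector vol, IntegerVector dim,
                                  double sigma) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> a(vol.begin(), vol.end());
  smooth_volume(a, nx, ny, nz, sigma);
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

// Sample a scalar volume at a matrix of 0-based voxel coordinates.
// [[Rcpp::export]]
NumericVector cpp_sample_scalar(NumericVector vol, IntegerVector dim,
                                NumericMatrix pts) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const double* v = vol.begin();
  int n = pts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = sample3(v, nx, ny, nz, pts(i, 0), pts(i, 1), pts(i, 2));
  return out;
}

// Sample a 3-vector field (nx*ny*nz*3, component-major blocks) at 0-based
// voxel coordinates; returns an n x 3 matrix (same units as the field).
// [[Rcpp::export]]
NumericMatrix cpp_sample_field(NumericVector field, IntegerVector dim,
                               NumericMatrix pts) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t N = (size_t)nx * ny * nz;
  int n = pts.nrow();
  NumericMatrix out(n, 3);
  for (int c = 0; c < 3; ++c) {
    const double* v = field.begin() + c * N;
    for (int i = 0; i < n; ++i)
      out(i, c) = sample3(v, nx, ny, nz, pts(i, 0), pts(i, 1), pts(i, 2));
  }
  return out;
}

// Warp a volume by a displacement field in voxel units: out(x) = vol(x + s(x)).
// [[Rcpp::export]]
NumericVector cpp_warp(NumericVector vol, IntegerVector dim,
                       NumericVector field) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t N = (size_t)nx * ny * nz;
  const double* v = vol.begin();
  const double* sx = field.begin();
  const double* sy = field.begin() + N;
  const double* sz = field.begin() + 2 * N;
  NumericVector out(N);
  size_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx)
        out[idx] = sample3(v, nx, ny, nz, i + sx[idx], j + sy[idx], k + sz[idx]);
  out.attr("dim") = dim;
  return out;
}

// Demons iterations at a single resolution level. fixed/moving are scalar
// volumes on the same grid; init is a displacement field in voxel units
// (may be all zeros). Returns the refined field s with
// moving(x + s(x)) ~ fixed(x). Symmetric force (mean of fixed and warped
// gradients), per-step cap, fluid and diffusion Gaussian regularization.
// [[Rcpp::export]]
NumericVector cpp_demons(NumericVector fixed, NumericVector moving,
                         IntegerVector dim, NumericVector init,
                         int iters, double sigma_fluid, double sigma_diff,
                         double step_max, double stop_tol,
                         NumericVector cond, int fluid_passes,
                         int diff_passes) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t N = (size_t)nx * ny * nz;
  const bool aniso = cond.size() == (R_xlen_t)N;
  std::vector<double> s(3 * N, 0.0);
  if (init.size() == (R_xlen_t)(3 * N))
    std::copy(init.begin(), init.end(), s.begin());
  std::vector<double> warped(N), ux(N), uy(N), uz(N);
  const double* F = fixed.begin();
  const double* M = moving.begin();
  const size_t SX = 1, SY = (size_t)nx, SZ = (size_t)nx * ny;

  for (int it = 0; it < iters; ++it) {
    // warp moving by current field
    size_t idx = 0;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i, ++idx)
          warped[idx] = sample3(M, nx, ny, nz, i + s[idx], j + s[idx + N],
                                k + s[idx + 2 * N]);
    // demons update
    double mean_step = 0.0;
    idx = 0;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i, ++idx) {
          int im = clampi(i - 1, 0, nx - 1), ip = clampi(i + 1, 0, nx - 1);
          int jm = clampi(j - 1, 0, ny - 1), jp = clampi(j + 1, 0, ny - 1);
          int km = clampi(k - 1, 0, nz - 1), kp = clampi(k + 1, 0, nz - 1);
          double gx = 0.25 * ((F[idx + (ip - i) * SX] - F[idx + (im - i) * SX]) +
                              (warped[idx + (ip - i) * SX] - warped[idx + (im - i) * SX]));
          double gy = 0.25 * ((F[idx + (jp - j) * SY] - F[idx + (jm - j) * SY]) +
                              (warped[idx + (jp - j) * SY] - warped[idx + (jm - j) * SY]));
          double gz = 0.25 * ((F[idx + (kp - k) * SZ] - F[idx + (km - k) * SZ]) +
                              (warped[idx + (kp - k) * SZ] - warped[idx + (km - k) * SZ]));
          double diff = F[idx] - warped[idx];
          double g2 = gx * gx + gy * gy + gz * gz;
          double denom = g2 + diff * diff;
          if (denom < 1e-9) { ux[idx] = uy[idx] = uz[idx] = 0.0; continue; }
          double fac = diff / denom;
          double vx = fac * gx, vy = fac * gy, vz = fac * gz;
          double mag = std::sqrt(vx * vx + vy * vy + vz * vz);
          if (mag > step_max) {
            double r = step_max / mag;
            vx *= r; vy *= r; vz *= r;
          }
          ux[idx] = vx; uy[idx] = vy; uz[idx] = vz;
          mean_step += std::sqrt(vx * vx + vy * vy + vz * vz);
        }
    mean_step /= (double)N;
    // fluid-like regularization of the update: edge-aware diffusion when
    // fluid_passes > 0 (no force transport across intensity boundaries),
    // otherwise Gaussian with sigma_fluid
    if (aniso && fluid_passes > 0) {
      aniso_smooth(ux, nx, ny, nz, cond.begin(), fluid_passes);
      aniso_smooth(uy, nx, ny, nz, cond.begin(), fluid_passes);
      aniso_smooth(uz, nx, ny, nz, cond.begin(), fluid_passes);
    } else {
      smooth_volume(ux, nx, ny, nz, sigma_fluid);
      smooth_volume(uy, nx, ny, nz, sigma_fluid);
      smooth_volume(uz, nx, ny, nz, sigma_fluid);
    }
    for (size_t t = 0; t < N; ++t) {
      s[t] += ux[t];
      s[t + N] += uy[t];
      s[t + 2 * N] += uz[t];
    }
    // diffusion-like regularization of the total field
    if (aniso) {
      std::vector<double> comp(N);
      for (int c = 0; c < 3; ++c) {
        std::copy(s.begin() + c * N, s.begin() + (c + 1) * N, comp.begin());
        aniso_smooth(comp, nx, ny, nz, cond.begin(), diff_passes);
        std::copy(comp.begin(), comp.end(), s.begin() + c * N);
      }
    } else if (sigma_diff > 0) {
      std::vector<double> comp(N);
      for (int c = 0; c < 3; ++c) {
        std::copy(s.begin() + c * N, s.begin() + (c + 1) * N, comp.begin());
        smooth_volume(comp, nx, ny, nz, sigma_diff);
        std::copy(comp.begin(), comp.end(), s.begin() + c * N);
      }
    }
    if (mean_step < stop_tol) break;
  }
  NumericVector out(s.begin(), s.end());
  out.attr("dim") = IntegerVector::create(nx, ny, nz, 3);
  return out;
}

// Jacobian determinant of the mapping x -> x + s(x) (field in voxel units),
// central differences, clamped at the boundary.
// [[Rcpp::export]]
NumericVector cpp_jacobian_det(NumericVector field, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t N = (size_t)nx * ny * nz;
  const double* s = field.begin();
  NumericVector out(N);
  const size_t SX = 1, SY = (size_t)nx, SZ = (size_t)nx * ny;
  size_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        int im = clampi(i - 1, 0, nx - 1), ip = clampi(i + 1, 0, nx - 1);
        int jm = clampi(j - 1, 0, ny - 1), jp = clampi(j + 1, 0, ny - 1);
        int km = clampi(k - 1, 0, nz - 1), kp = clampi(k + 1, 0, nz - 1);
        double hx = 0.5 * (ip - im), hy = 0.5 * (jp - jm), hz = 0.5 * (kp - km);
        double J[3][3];
        for (int c = 0; c < 3; ++c) {
          const double* sc = s + (size_t)c * N;
          J[c][0] = (sc[idx + (ip - i) * SX] - sc[idx + (im - i) * SX]) / (2 * hx);
          J[c][1] = (sc[idx + (jp - j) * SY] - sc[idx + (jm - j) * SY]) / (2 * hy);
          J[c][2] = (sc[idx + (kp - k) * SZ] - sc[idx + (km - k) * SZ]) / (2 * hz);
        }
        J[0][0] += 1.0; J[1][1] += 1.0; J[2][2] += 1.0;
        out[idx] = J[0][0] * (J[1][1] * J[2][2] - J[1][2] * J[2][1]) -
                   J[0][1] * (J[1][0] * J[2][2] - J[1][2] * J[2][0]) +
                   J[0][2] * (J[1][0] * J[2][1] - J[1][1] * J[2][0]);
      }
  out.attr("dim") = IntegerVector::create(nx, ny, nz);
  return out;
}

// Fixed-point inversion: find v with (x + s)(y + v(y)) = y, i.e.
// v(y) = -s(y + v(y)). Field and result in voxel units.
// [[Rcpp::export]]
NumericVector cpp_invert_field(NumericVector field, IntegerVector dim,
                               int iters, double tol) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t N = (size_t)nx * ny * nz;
  const double* sx = field.begin();
  const double* sy = field.begin() + N;
  const double* sz = field.begin() + 2 * N;
  std::vector<double> v(3 * N, 0.0);
  for (int it = 0; it < iters; ++it) {
    double max_move = 0.0;
    size_t idx = 0;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i, ++idx) {
          double px = i + v[idx], py = j + v[idx + N], pz = k + v[idx + 2 * N];
          double nvx = -sample3(sx, nx, ny, nz, px, py, pz);
          double nvy = -sample3(sy, nx, ny, nz, px, py, pz);
          double nvz = -sample3(sz, nx, ny, nz, px, py, pz);
          double dx = nvx - v[idx], dy = nvy - v[idx + N], dz = nvz - v[idx + 2 * N];
          double m = std::sqrt(dx * dx + dy * dy + dz * dz);
          if (m > max_move) max_move = m;
          v[idx] = nvx; v[idx + N] = nvy; v[idx + 2 * N] = nvz;
        }
    if (max_move < tol) break;
  }
  NumericVector out(v.begin(), v.end());
  out.attr("dim") = IntegerVector::create(nx, ny, nz, 3);
  return out;
}

// Block-mean 2x downsampling (partial blocks averaged at the far edges).
// [[Rcpp::export]]
NumericVector cpp_downsample2(NumericVector vol, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int ox = (nx + 1) / 2, oy = (ny + 1) / 2, oz = (nz + 1) / 2;
  const double* v = vol.begin();
  NumericVector out((size_t)ox * oy * oz);
  const size_t SY = (size_t)nx, SZ = (size_t)nx * ny;
  size_t odx = 0;
  for (int k = 0; k < oz; ++k)
    for (int j = 0; j < oy; ++j)
      for (int i = 0; i < ox; ++i, ++odx) {
        double acc = 0.0;
        int cnt = 0;
        for (int dk = 0; dk < 2; ++dk)
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              int ii = 2 * i + di, jj = 2 * j + dj, kk = 2 * k + dk;
              if (ii < nx && jj < ny && kk < nz) {
                acc += v[ii + jj * SY + kk * SZ];
                ++cnt;
              }
            }
        out[odx] = acc / cnt;
      }
  out.attr("dim") = IntegerVector::create(ox, oy, oz);
  return out;
}

// Exhaustive nearest-point search: for each query row, the index (1-based)
// of the closest reference row in Euclidean distance; ties broken by the
// smallest reference index (strict < comparison keeps the first minimum).
// [[Rcpp::export]]
List cpp_nearest(NumericMatrix query, NumericMatrix ref) {
  int n = query.nrow(), m = ref.nrow();
  IntegerVector idx(n);
  NumericVector dist(n);
  std::vector<double> rx(m), ry(m), rz(m);
  for (int j = 0; j < m; ++j) {
    rx[j] = ref(j, 0); ry[j] = ref(j, 1); rz[j] = ref(j, 2);
  }
  for (int i = 0; i < n; ++i) {
    double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    double best = R_PosInf;
    int bj = 0;
    for (int j = 0; j < m; ++j) {
      double dx = qx - rx[j], dy = qy - ry[j], dz = qz - rz[j];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; bj = j; }
    }
    idx[i] = bj + 1;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}

// 26-connected component labelling of a logical mask. Returns an integer
// array with 0 = background and components numbered from 1 in scan order.
// [[Rcpp::export]]
IntegerVector cpp_label26(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t N = (size_t)nx * ny * nz;
  IntegerVector lab(N);
  const int* m = mask.begin();
  std::vector<size_t> stack;
  int next = 0;
  const size_t SY = (size_t)nx, SZ = (size_t)nx * ny;
  for (size_t start = 0; start < N; ++start) {
    if (!m[start] || lab[start] != 0) continue;
    ++next;
    lab[start] = next;
    stack.clear();
    stack.push_back(start);
    while (!stack.empty()) {
      size_t cur = stack.back();
      stack.pop_back();
      int i = (int)(cur % nx);
      int j = (int)((cur / nx) % ny);
      int k = (int)(cur / SZ);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;
            size_t nb = (size_t)ii + (size_t)jj * SY + (size_t)kk * SZ;
            if (m[nb] && lab[nb] == 0) {
              lab[nb] = next;
              stack.push_back(nb);
            }
          }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}
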