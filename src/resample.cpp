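#include <Rcpp.h>
using namespace Rcpp;

static inline double get_or(const double *v, int nx, int ny, int nz,
                            int i, int j, int k, double outside) {
  if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return outside;
  return v[i + (size_t)nx * (j + (size_t)ny * k)];
}

// Sample a 3D volume at fractional 0-based voxel coordinates.
// mode 0 = trilinear, 1 = nearest. If clamp_edge, coordinates are clamped to
// the grid (used for displacement-field lookups); otherwise out-of-grid
// neighbours contribute `outside`.
// [[Rcpp::export]]
NumericVector cpp_sample3(NumericVector vol, IntegerVector dim,
                          NumericVector x, NumericVector y, NumericVector z,
                          int mode, double outside, bool clamp_edge) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double *v = vol.begin();
  const R_xlen_t n = x.size();
  NumericVector out(n);
  for (R_xlen_t p = 0; p < n; ++p) {
    double xi = x[p], yj = y[p], zk = z[p];
    if (clamp_edge) {
      xi = std::min(std::max(xi, 0.0), (double)(nx - 1));
      yj = std::min(std::max(yj, 0.0), (double)(ny - 1));
      zk = std::min(std::max(zk, 0.0), (double)(nz - 1));
    }
    if (mode == 1) {
      int i = (int)std::lround(xi), j = (int)std::lround(yj), k = (int)std::lround(zk);
      out[p] = get_or(v, nx, ny, nz, i, j, k, outside);
      continue;
    }
    int i0 = (int)std::floor(xi), j0 = (int)std::floor(yj), k0 = (int)std::floor(zk);
    double fx = xi - i0, fy = yj - j0, fz = zk - k0;
    double acc = 0.0;
    for (int dk = 0; dk <= 1; ++dk) {
      double wz = dk ? fz : 1.0 - fz;
      if (wz == 0.0) continue;
      for (int dj = 0; dj <= 1; ++dj) {
        double wy = dj ? fy : 1.0 - fy;
        if (wy == 0.0) continue;
        for (int di = 0; di <= 1; ++di) {
          double wx = di ? fx : 1.0 - fx;
          if (wx == 0.0) continue;
          acc += wx * wy * wz *
            get_or(v, nx, ny, nz, i0 + di, j0 + dj, k0 + dk, outside);
        }
      }
    }
    out[p] = acc;
  }
  return out;
}

static void blur_axis(std::vector<double> &src, std::vector<double> &dst,
                      int nx, int ny, int nz, int axis, double sigma) {
  int radius = (int)std::ceil(3.0 * sigma);
  if (radius < 1) radius = 1;
  std::vector<double> kern(2 * radius + 1);
  double s = 0.0;
  for (int t = -radius; t <= radius; ++t) {
    kern[t + radius] = std::exp(-0.5 * (double)t * t / (sigma * sigma));
    s += kern[t + radius];
  }
  for (double &w : kern) w /= s;
  const int n[3] = {nx, ny, nz};
  const size_t stride[3] = {1, (size_t)nx, (size_t)nx * ny};
  const int na = n[axis];
  const size_t sa = stride[axis];
  // iterate over all lines along `axis`
  int b1 = (axis == 0) ? 1 : 0;
  int b2 = (axis == 2) ? 1 : 2;
  for (int q = 0; q < n[b2]; ++q) {
    for (int p = 0; p < n[b1]; ++p) {
      size_t base = (size_t)p * stride[b1] + (size_t)q * stride[b2];
      for (int i = 0; i < na; ++i) {
        double acc = 0.0;
        for (int t = -radius; t <= radius; ++t) {
          int ii = i + t;
          if (ii < 0) ii = -ii;                 // reflect
          if (ii >= na) ii = 2 * na - 2 - ii;
          if (ii < 0) ii = 0;
          acc += kern[t + radius] * src[base + (size_t)ii * sa];
        }
        dst[base + (size_t)i * sa] = acc;
      }
    }
  }
}

// Separable Gaussian smoothing, sigma per axis in voxels, reflect boundary.
// [[Rcpp::export]]
NumericVector cpp_gauss3(NumericVector vol, IntegerVector dim, NumericVector sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> a(vol.begin(), vol.end()), b(a.size());
  for (int axis = 0; axis < 3; ++axis) {
    if (sigma[axis] > 0.0) {
      blur_axis(a, b, nx, ny, nz, axis, sigma[axis]);
      a.swap(b);
    }
  }
  NumericVector out(vol.size());
  std::copy(a.begin(), a.end(), out.begin());
  out.attr("dim") = dim;
  return out;
}

// Central-difference gradient (one-sided at the edges), per-axis spacing in mm.
// Returns the three components concatenated (nx*ny*nz each).
// [[Rcpp::export]]
NumericVector cpp_grad3(NumericVector vol, IntegerVector dim, NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t nvox = (size_t)nx * ny * nz;
  const double *v = vol.begin();
  NumericVector out(3 * nvox);
  double *g = out.begin();
  const int n[3] = {nx, ny, nz};
  const ptrdiff_t stride[3] = {1, (ptrdiff_t)nx, (ptrdiff_t)nx * ny};
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        ptrdiff_t idx = i + (ptrdiff_t)nx * (j + (ptrdiff_t)ny * k);
        int ijk[3] = {i, j, k};
        for (int a = 0; a < 3; ++a) {
          int lo = ijk[a] > 0 ? -1 : 0;
          int hi = ijk[a] < n[a] - 1 ? 1 : 0;
          if (hi == lo) { g[a * nvox + idx] = 0.0; continue; }
          double num = v[idx + hi * stride[a]] - v[idx + lo * stride[a]];
          g[a * nvox + idx] = num / ((hi - lo) * spacing[a]);
        }
      }
  return out;
}
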