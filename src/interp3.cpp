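// Volume interpolation at arbitrary continuous voxel coordinates.
// order 1: trilinear. order 3: separable Catmull-Rom cubic convolution,
// whose flat pass-band preserves wall undulations at the few-voxel
// wavelengths that trilinear interpolation visibly attenuates.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double catmull_rom(double p0, double p1, double p2, double p3, double t) {
  return p1 + 0.5 * t * (p2 - p0 +
         t * (2.0 * p0 - 5.0 * p1 + 4.0 * p2 - p3 +
         t * (3.0 * (p1 - p2) + p3 - p0)));
}

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// vox: volume values; dims: grid dims; pts: n x 3 continuous 0-based voxel
// coordinates; outside: value for points beyond the grid.
// [[Rcpp::export(name = ".interp3")]]
NumericVector interp3(NumericVector vox, IntegerVector dims, NumericMatrix pts,
                      int order, double outside) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = pts.nrow();
  NumericVector out(n);
  R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  for (R_xlen_t p = 0; p < n; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
      out[p] = outside;
      continue;
    }
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    if (i0 > nx - 2) i0 = nx - 2;
    if (j0 > ny - 2) j0 = ny - 2;
    if (k0 > nz - 2) k0 = nz - 2;
    double fx = x - i0, fy = y - j0, fz = z - k0;
    if (order == 1) {
      R_xlen_t b = i0 * sx + j0 * sy + k0 * sz;
      double c00 = vox[b] * (1 - fx) + vox[b + sx] * fx;
      double c10 = vox[b + sy] * (1 - fx) + vox[b + sx + sy] * fx;
      double c01 = vox[b + sz] * (1 - fx) + vox[b + sx + sz] * fx;
      double c11 = vox[b + sy + sz] * (1 - fx) + vox[b + sx + sy + sz] * fx;
      out[p] = (c00 * (1 - fy) + c10 * fy) * (1 - fz) +
               (c01 * (1 - fy) + c11 * fy) * fz;
    } else {
      double zq[4];
      for (int dk = -1; dk <= 2; ++dk) {
        int k = clampi(k0 + dk, 0, nz - 1);
        double yq[4];
        for (int dj = -1; dj <= 2; ++dj) {
          int j = clampi(j0 + dj, 0, ny - 1);
          R_xlen_t b = j * sy + (R_xlen_t)k * sz;
          double xq[4];
          for (int di = -1; di <= 2; ++di)
            xq[di + 1] = vox[b + clampi(i0 + di, 0, nx - 1)];
          yq[dj + 1] = catmull_rom(xq[0], xq[1], xq[2], xq[3], fx);
        }
        zq[dk + 1] = catmull_rom(yq[0], yq[1], yq[2], yq[3], fy);
      }
      out[p] = catmull_rom(zq[0], zq[1], zq[2], zq[3], fz);
    }
  }
  return out;
}
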