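#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Felzenszwalb & Huttenlocher lower-envelope 1-D squared distance transform.
// f: input squared distances at n samples with physical step `h`; d: output.
static void dt1d(const double* f, double* d, int n, double h,
                 std::vector<int>& v, std::vector<double>& z) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; q++) {
    double s;
    for (;;) {
      double qq = q * h, vv = v[k] * h;
      s = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) / (2.0 * qq - 2.0 * vv);
      if (s <= z[k]) { k--; } else break;
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    double qq = q * h;
    while (z[k + 1] < qq) k++;
    double diff = qq - v[k] * h;
    d[q] = diff * diff + f[v[k]];
  }
}

// Squared Euclidean distance (mm^2) from every voxel to the nearest TRUE
// voxel centre of `mask` (3-D, isotropic spacing). Voxels inside the mask
// get 0. A large finite sentinel stands in for infinity: the parabola
// intersections of the lower-envelope algorithm are undefined for true
// IEEE infinities (INF - INF).
// [[Rcpp::export]]
NumericVector edt_sq_cpp(LogicalVector mask, IntegerVector dim, double spacing) {
  const double BIG = 1e20;
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++)
    out[i] = (mask[i] == TRUE) ? 0.0 : BIG;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x (fastest-varying)
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++) {
      double* row = &out[(R_xlen_t)k * nx * ny + (R_xlen_t)j * nx];
      dt1d(row, d.data(), nx, spacing, v, z);
      std::copy(d.begin(), d.begin() + nx, row);
    }
  // pass along y
  for (int k = 0; k < nz; k++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + i;
      for (int j = 0; j < ny; j++) f[j] = out[base + (R_xlen_t)j * nx];
      dt1d(f.data(), d.data(), ny, spacing, v, z);
      for (int j = 0; j < ny; j++) out[base + (R_xlen_t)j * nx] = d[j];
    }
  // pass along z
  R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; j++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = (R_xlen_t)j * nx + i;
      for (int k = 0; k < nz; k++) f[k] = out[base + (R_xlen_t)k * nxy];
      dt1d(f.data(), d.data(), nz, spacing, v, z);
      for (int k = 0; k < nz; k++) out[base + (R_xlen_t)k * nxy] = d[k];
    }
  return out;
}

static inline double sample_clamped(const double* a, int nx, int ny, int nz,
                                    double x, double y, double z) {
  // clamp-to-edge trilinear interpolation at 0-based voxel coordinates
  if (x < 0) x = 0; if (x > nx - 1) x = nx - 1;
  if (y < 0) y = 0; if (y > ny - 1) y = ny - 1;
  if (z < 0) z = 0; if (z > nz - 1) z = nz - 1;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  if (x0 > nx - 2) x0 = nx > 1 ? nx - 2 : 0;
  if (y0 > ny - 2) y0 = ny > 1 ? ny - 2 : 0;
  if (z0 > nz - 2) z0 = nz > 1 ? nz - 2 : 0;
  int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
      z1 = std::min(z0 + 1, nz - 1);
  double wx = x - x0, wy = y - y0, wz = z - z0;
  R_xlen_t nxy = (R_xlen_t)nx * ny;
  #define V(i, j, k) a[(R_xlen_t)(k) * nxy + (R_xlen_t)(j) * nx + (i)]
  double c00 = V(x0, y0, z0) * (1 - wx) + V(x1, y0, z0) * wx;
  double c10 = V(x0, y1, z0) * (1 - wx) + V(x1, y1, z0) * wx;
  double c01 = V(x0, y0, z1) * (1 - wx) + V(x1, y0, z1) * wx;
  double c11 = V(x0, y1, z1) * (1 - wx) + V(x1, y1, z1) * wx;
  #undef V
  double c0 = c00 * (1 - wy) + c10 * wy;
  double c1 = c01 * (1 - wy) + c11 * wy;
  return c0 * (1 - wz) + c1 * wz;
}

// Resample a whole volume at x - shift (shift in voxel units), i.e. a rigid
// translation of the field by +shift, clamp-to-edge outside the grid.
// [[Rcpp::export]]
NumericVector resample_shift_cpp(NumericVector values, IntegerVector dim,
                                 NumericVector shift_vox) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double sx = shift_vox[0], sy = shift_vox[1], sz = shift_vox[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  const double* a = values.begin();
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++)
        out[idx++] = sample_clamped(a, nx, ny, nz, i - sx, j - sy, k - sz);
  return out;
}

// Trilinear samples at arbitrary 0-based voxel coordinates (n x 3 matrix),
// clamp-to-edge.
// [[Rcpp::export]]
NumericVector sample_points_cpp(NumericVector values, IntegerVector dim,
                                NumericMatrix pts) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = pts.nrow();
  NumericVector out(n);
  const double* a = values.begin();
  for (R_xlen_t q = 0; q < n; q++)
    out[q] = sample_clamped(a, nx, ny, nz, pts(q, 0), pts(q, 1), pts(q, 2));
  return out;
}
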