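#include <Rcpp.h>
#include <vector>
#include <cmath>

// Separable squared Euclidean distance transform (Felzenszwalb & Huttenlocher)
// with anisotropic voxel spacing. Input: logical/integer mask (non-zero =
// foreground); output: distance in physical units (mm) from every voxel to
// the nearest foreground voxel (0 inside the mask, Inf if the mask is empty).
// Background cells carry a large finite sentinel instead of +Inf so the
// lower-envelope recursion stays well defined.

static const double BIG = 1e15;

static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 double step) {
  const int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  const double step2 = step * step;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + step2 * q * q) - (f[v[k]] + step2 * v[k] * v[k])) /
               (2.0 * step2 * (q - v[k]));
    while (s <= z[k]) {
      --k;
      s = ((f[q] + step2 * q * q) - (f[v[k]] + step2 * v[k] * v[k])) /
          (2.0 * step2 * (q - v[k]));
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = BIG;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    while (z[j + 1] < q) ++j;
    double dq = step * (q - v[j]);
    d[q] = dq * dq + f[v[j]];
  }
}

// [[Rcpp::export]]
Rcpp::NumericVector edt3d_cpp(Rcpp::IntegerVector mask, Rcpp::IntegerVector dims,
                              Rcpp::NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> d((size_t)n);
  for (R_xlen_t i = 0; i < n; ++i) d[(size_t)i] = mask[i] != 0 ? 0.0 : BIG;

  std::vector<double> f, g;
  f.resize(nx); g.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t off = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; ++x) f[x] = d[off + x];
      dt1d(f, g, spacing[0]);
      for (int x = 0; x < nx; ++x) d[off + x] = g[x];
    }
  f.resize(ny); g.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t off = (R_xlen_t)z * nx * ny + x;
      for (int y = 0; y < ny; ++y) f[y] = d[off + (R_xlen_t)y * nx];
      dt1d(f, g, spacing[1]);
      for (int y = 0; y < ny; ++y) d[off + (R_xlen_t)y * nx] = g[y];
    }
  f.resize(nz); g.resize(nz);
  const R_xlen_t plane = (R_xlen_t)nx * ny;
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t off = (R_xlen_t)y * nx + x;
      for (int z = 0; z < nz; ++z) f[z] = d[off + (R_xlen_t)z * plane];
      dt1d(f, g, spacing[2]);
      for (int z = 0; z < nz; ++z) d[off + (R_xlen_t)z * plane] = g[z];
    }

  Rcpp::NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = d[(size_t)i];
    out[i] = (v >= BIG / 2) ? R_PosInf : std::sqrt(v);
  }
  out.attr("dim") = dims;
  return out;
}
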