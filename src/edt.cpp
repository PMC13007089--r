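#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Felzenszwalb & Huttenlocher lower-envelope distance transform of a
// 1D sampled function, generalized to non-unit sample spacing `w` (mm).
// `f` holds squared distances on entry and exit. Background lines (all
// entries at BIG) pass through unchanged; BIG is large enough that a
// parabola rooted at a BIG sample can never undercut a real one within
// any realistic field of view, yet small enough that the intersection
// arithmetic stays exact to well below 1e-9 mm.
static const double BIG = 1e15;

static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z,
                 const int n, const double w) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  const double w2 = w * w;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
               (2.0 * w * (q - v[k]));
    while (s <= z[k]) {
      --k;
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
          (2.0 * w * (q - v[k]));
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < w * q) ++k;
    const double dq = w * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt_cpp")]]
NumericVector edt_cpp(LogicalVector mask, IntegerVector dim,
                      NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  // squared distance, seeded from the mask
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : BIG;

  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x (stride 1)
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      const R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; ++i) f[i] = out[base + i];
      dt1d(f, d, v, z, nx, spacing[0]);
      for (int i = 0; i < nx; ++i) out[base + i] = d[i];
    }
  // pass along y (stride nx)
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      const R_xlen_t base = i + (R_xlen_t)nx * ny * k;
      for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)nx * j];
      dt1d(f, d, v, z, ny, spacing[1]);
      for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)nx * j] = d[j];
    }
  // pass along z (stride nx*ny)
  const R_xlen_t sz = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      const R_xlen_t base = i + (R_xlen_t)nx * j;
      for (int k = 0; k < nz; ++k) f[k] = out[base + sz * k];
      dt1d(f, d, v, z, nz, spacing[2]);
      for (int k = 0; k < nz; ++k) out[base + sz * k] = d[k];
    }

  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(out[i]);
  return out;
}
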