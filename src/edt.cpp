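#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// squared distances above this are treated as "no source" (empty input)
static const double BIG = 1e300;

// 1D squared-distance transform (lower envelope of parabolas), sample pitch
// w along this axis. f: input squared distances, d: output.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 double w) {
  const int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  const double w2 = w * w;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
               (2.0 * w2 * (q - v[k]));
    while (s <= z[k]) {
      --k;
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = w2 * (q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// Exact Euclidean distance transform of a 3D mask: for every voxel, the
// distance (world units) to the nearest set voxel center; NA if the mask is
// empty along all axes. spacing gives the voxel pitch per axis.
// [[Rcpp::export(name = ".edt3d")]]
NumericVector edt3d(LogicalVector mask, IntegerVector dims,
                    NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> d(n);
  for (R_xlen_t t = 0; t < n; ++t) d[t] = mask[t] ? 0.0 : BIG;

  auto idx = [nx, ny](int x, int y, int z) {
    return (R_xlen_t)x + (R_xlen_t)nx * ((R_xlen_t)y + (R_xlen_t)ny * z);
  };

  std::vector<double> f, out;
  f.resize(nx); out.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) f[x] = d[idx(x, y, z)];
      dt1d(f, out, spacing[0]);
      for (int x = 0; x < nx; ++x) d[idx(x, y, z)] = out[x];
    }
  f.resize(ny); out.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) f[y] = d[idx(x, y, z)];
      dt1d(f, out, spacing[1]);
      for (int y = 0; y < ny; ++y) d[idx(x, y, z)] = out[y];
    }
  f.resize(nz); out.resize(nz);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int z = 0; z < nz; ++z) f[z] = d[idx(x, y, z)];
      dt1d(f, out, spacing[2]);
      for (int z = 0; z < nz; ++z) d[idx(x, y, z)] = out[z];
    }

  NumericVector res(n);
  for (R_xlen_t t = 0; t < n; ++t)
    res[t] = (d[t] >= BIG / 2) ? NA_REAL : std::sqrt(d[t]);
  res.attr("dim") = dims;
  return res;
}
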