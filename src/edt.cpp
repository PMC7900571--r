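#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// Exact 1-D squared-distance transform (lower envelope of parabolas),
// sample spacing s. f holds squared distances on input; overwritten.
// Infinite entries (no feature on this line yet) are skipped as parabola
// sources but still receive propagated distances.
static void dt1d(std::vector<double> &f, std::vector<int> &v,
                 std::vector<double> &z, std::vector<double> &d, double s) {
  const int n = (int)f.size();
  const double inf = std::numeric_limits<double>::infinity();
  if (n <= 1) return;

  int q0 = -1;
  for (int q = 0; q < n; ++q)
    if (f[q] < inf) { q0 = q; break; }
  if (q0 < 0) return;  // whole line infinite: nothing to propagate

  const double s2 = s * s;
  int k = 0;
  v[0] = q0;
  z[0] = -inf;
  z[1] = inf;
  for (int q = q0 + 1; q < n; ++q) {
    if (f[q] == inf) continue;
    int p = v[k];
    double sint = ((f[q] + s2 * q * q) - (f[p] + s2 * p * p)) /
                  (2.0 * s2 * (q - p));
    while (sint <= z[k]) {
      --k;
      p = v[k];
      sint = ((f[q] + s2 * q * q) - (f[p] + s2 * p * p)) /
             (2.0 * s2 * (q - p));
    }
    ++k;
    v[k] = q;
    z[k] = sint;
    z[k + 1] = inf;
  }

  int j = 0;
  for (int q = 0; q < n; ++q) {
    while (z[j + 1] < q) ++j;
    const double dq = s * (q - v[j]);
    d[q] = dq * dq + f[v[j]];
  }
  for (int q = 0; q < n; ++q) f[q] = d[q];
}

// Squared Euclidean distance (physical units) from every voxel centre to
// the nearest TRUE voxel centre of `feature`. Column-major 3-D array with
// per-axis spacing. Returns +Inf everywhere if the feature set is empty.
// [[Rcpp::export(name = ".edt_sq")]]
NumericVector edt_sq(LogicalVector feature, IntegerVector dim, NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double inf = std::numeric_limits<double>::infinity();
  NumericVector out(feature.size());
  for (R_xlen_t i = 0; i < feature.size(); ++i)
    out[i] = feature[i] ? 0.0 : inf;

  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> line(nmax), z(nmax + 1), d(nmax);
  std::vector<int> v(nmax);

  // pass along x
  line.resize(nx);
  for (int z3 = 0; z3 < nz; ++z3)
    for (int y = 0; y < ny; ++y) {
      const R_xlen_t base = (R_xlen_t)z3 * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; ++x) line[x] = out[base + x];
      dt1d(line, v, z, d, spacing[0]);
      for (int x = 0; x < nx; ++x) out[base + x] = line[x];
    }
  // pass along y
  line.resize(ny);
  for (int z3 = 0; z3 < nz; ++z3)
    for (int x = 0; x < nx; ++x) {
      const R_xlen_t base = (R_xlen_t)z3 * nx * ny + x;
      for (int y = 0; y < ny; ++y) line[y] = out[base + (R_xlen_t)y * nx];
      dt1d(line, v, z, d, spacing[1]);
      for (int y = 0; y < ny; ++y) out[base + (R_xlen_t)y * nx] = line[y];
    }
  // pass along z
  line.resize(nz);
  const R_xlen_t plane = (R_xlen_t)nx * ny;
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      const R_xlen_t base = (R_xlen_t)y * nx + x;
      for (int z3 = 0; z3 < nz; ++z3) line[z3] = out[base + (R_xlen_t)z3 * plane];
      dt1d(line, v, z, d, spacing[2]);
      for (int z3 = 0; z3 < nz; ++z3) out[base + (R_xlen_t)z3 * plane] = line[z3];
    }
  return out;
}
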