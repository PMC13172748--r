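#include <Rcpp.h>
#include <vector>
#include <limits>

// Exact Euclidean distance transform for a 3-D binary grid with anisotropic
// voxel spacing, via the separable lower-envelope-of-parabolas algorithm
// (Felzenszwalb & Huttenlocher). Works on squared distances; one 1-D pass
// per axis. A large finite constant stands in for infinity so the envelope
// arithmetic never produces NaN.

static const double BIG = 1e20;

// 1-D squared distance transform along a line of n samples with spacing h.
// f: input squared distances; d: output; v/z: work arrays (size n, n+1).
static void dt1d(const double *f, double *d, int *v, double *z, int n,
                 double h2) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + h2 * q * q) - (f[v[k]] + h2 * (double)v[k] * v[k])) /
               (2.0 * h2 * (q - v[k]));
    while (s <= z[k]) {
      k--;
      s = ((f[q] + h2 * q * q) - (f[v[k]] + h2 * (double)v[k] * v[k])) /
          (2.0 * h2 * (q - v[k]));
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = (double)(q - v[k]);
    d[q] = h2 * dq * dq + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt_squared")]]
Rcpp::NumericVector edt_squared(Rcpp::LogicalVector mask,
                                Rcpp::IntegerVector dims,
                                Rcpp::NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  Rcpp::NumericVector out(n);

  // seed: 0 inside the structure, "infinite" outside
  for (R_xlen_t i = 0; i < n; i++) out[i] = (mask[i] == TRUE) ? 0.0 : BIG;

  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x (fastest-varying index)
  for (int kz = 0; kz < nz; kz++)
    for (int ky = 0; ky < ny; ky++) {
      const R_xlen_t base = (R_xlen_t)kz * nx * ny + (R_xlen_t)ky * nx;
      for (int q = 0; q < nx; q++) f[q] = out[base + q];
      dt1d(f.data(), d.data(), v.data(), z.data(), nx, spacing[0] * spacing[0]);
      for (int q = 0; q < nx; q++) out[base + q] = d[q];
    }

  // pass along y
  for (int kz = 0; kz < nz; kz++)
    for (int kx = 0; kx < nx; kx++) {
      const R_xlen_t base = (R_xlen_t)kz * nx * ny + kx;
      for (int q = 0; q < ny; q++) f[q] = out[base + (R_xlen_t)q * nx];
      dt1d(f.data(), d.data(), v.data(), z.data(), ny, spacing[1] * spacing[1]);
      for (int q = 0; q < ny; q++) out[base + (R_xlen_t)q * nx] = d[q];
    }

  // pass along z
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int ky = 0; ky < ny; ky++)
    for (int kx = 0; kx < nx; kx++) {
      const R_xlen_t base = (R_xlen_t)ky * nx + kx;
      for (int q = 0; q < nz; q++) f[q] = out[base + (R_xlen_t)q * nxy];
      dt1d(f.data(), d.data(), v.data(), z.data(), nz, spacing[2] * spacing[2]);
      for (int q = 0; q < nz; q++) out[base + (R_xlen_t)q * nxy] = d[q];
    }

  out.attr("dim") = dims;
  return out;
}
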