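#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exact Euclidean distance transform on a 3D grid, computed with the
// separable lower-envelope-of-parabolas algorithm (one 1D pass per axis on
// squared distances). Anisotropic voxel spacing enters as a per-axis
// coordinate scale, so distances come out in the units of `spacing`
// (voxel units when spacing is all ones, millimetres otherwise).

static const double BIG = 1e20;

// 1D squared-distance transform of sampled function f at sites x_i = i*s.
static void dt1d(const double* f, double* d, int n, double s,
                 std::vector<int>& v, std::vector<double>& z) {
  if (n == 1) { d[0] = f[0]; return; }
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; ++q) {
    const double xq = q * s;
    double xs, sep;
    for (;;) {
      const double xv = v[k] * s;
      xs = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (xs <= z[k] && k > 0) {
        --k;
      } else {
        sep = xs;
        break;
      }
    }
    if (k == 0 && sep <= z[0]) {
      // q's parabola dominates everywhere seen so far
      v[0] = q;
      z[1] = BIG;
    } else {
      ++k;
      v[k] = q;
      z[k] = sep;
      z[k + 1] = BIG;
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    const double xq = q * s;
    while (z[k + 1] < xq) ++k;
    const double dx = xq - v[k] * s;
    d[q] = dx * dx + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector edt3d_cpp(LogicalVector seeds, IntegerVector dim,
                        NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  NumericVector out(ntot);
  double* g = out.begin();
  for (R_xlen_t i = 0; i < ntot; ++i) g[i] = seeds[i] ? 0.0 : BIG;

  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x (stride 1)
  for (int kz = 0; kz < nz; ++kz)
    for (int ky = 0; ky < ny; ++ky) {
      double* line = g + (R_xlen_t)nx * (ky + (R_xlen_t)ny * kz);
      dt1d(line, d.data(), nx, spacing[0], v, z);
      std::copy(d.begin(), d.begin() + nx, line);
    }
  // pass along y (stride nx)
  for (int kz = 0; kz < nz; ++kz)
    for (int kx = 0; kx < nx; ++kx) {
      double* base = g + kx + (R_xlen_t)nx * ny * kz;
      for (int ky = 0; ky < ny; ++ky) f[ky] = base[(R_xlen_t)nx * ky];
      dt1d(f.data(), d.data(), ny, spacing[1], v, z);
      for (int ky = 0; ky < ny; ++ky) base[(R_xlen_t)nx * ky] = d[ky];
    }
  // pass along z (stride nx*ny)
  const R_xlen_t sxy = (R_xlen_t)nx * ny;
  for (int ky = 0; ky < ny; ++ky)
    for (int kx = 0; kx < nx; ++kx) {
      double* base = g + kx + (R_xlen_t)nx * ky;
      for (int kz = 0; kz < nz; ++kz) f[kz] = base[sxy * kz];
      dt1d(f.data(), d.data(), nz, spacing[2], v, z);
      for (int kz = 0; kz < nz; ++kz) base[sxy * kz] = d[kz];
    }

  for (R_xlen_t i = 0; i < ntot; ++i) g[i] = std::sqrt(g[i]);
  return out;
}
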