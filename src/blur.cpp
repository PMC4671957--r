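#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Accumulate truncated, unit-mass Gaussian kernels at atom positions onto a
// regular grid. Voxel (i, j, k) (0-based) has its centre at
// origin + (i, j, k) * voxel. Each atom contributes
//   voxel^3 / ((2*pi)^{3/2} sigma^3) * exp(-r^2 / (2 sigma^2))
// within the cutoff radius, so an untruncated atom sums to ~1 over the grid.
// [[Rcpp::export]]
NumericVector cpp_blur_atoms(NumericMatrix coords, IntegerVector dims,
                             NumericVector origin, double voxel,
                             double sigma, double cutoff) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  out.attr("dim") = dims;
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const double amp = std::pow(voxel, 3.0) /
      (std::pow(2.0 * M_PI, 1.5) * std::pow(sigma, 3.0));
  const double c2 = cutoff * cutoff;
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  for (int a = 0; a < coords.nrow(); ++a) {
    const double ax = coords(a, 0), ay = coords(a, 1), az = coords(a, 2);
    int ix0 = (int)std::ceil((ax - cutoff - ox) / voxel);
    int ix1 = (int)std::floor((ax + cutoff - ox) / voxel);
    int iy0 = (int)std::ceil((ay - cutoff - oy) / voxel);
    int iy1 = (int)std::floor((ay + cutoff - oy) / voxel);
    int iz0 = (int)std::ceil((az - cutoff - oz) / voxel);
    int iz1 = (int)std::floor((az + cutoff - oz) / voxel);
    if (ix0 < 0) ix0 = 0; if (ix1 > nx - 1) ix1 = nx - 1;
    if (iy0 < 0) iy0 = 0; if (iy1 > ny - 1) iy1 = ny - 1;
    if (iz0 < 0) iz0 = 0; if (iz1 > nz - 1) iz1 = nz - 1;
    for (int iz = iz0; iz <= iz1; ++iz) {
      const double dz = oz + iz * voxel - az;
      for (int iy = iy0; iy <= iy1; ++iy) {
        const double dy = oy + iy * voxel - ay;
        const double dyz2 = dy * dy + dz * dz;
        const R_xlen_t base = (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
        for (int ix = ix0; ix <= ix1; ++ix) {
          const double dx = ox + ix * voxel - ax;
          const double r2 = dx * dx + dyz2;
          if (r2 <= c2) out[base + ix] += amp * std::exp(-r2 * inv2s2);
        }
      }
    }
  }
  return out;
}
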