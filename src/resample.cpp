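// Box resampling used by the per-tooth cropper: maps an axis-aligned box of
// the input grid (continuous index space, voxel centers at integers 1..n)
// onto a regular output grid, sampling trilinearly (images) or by nearest
// neighbour (label masks), with clamping at the volume border.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector resample_box_cpp(NumericVector vol, IntegerVector dims,
                               NumericVector lo, NumericVector hi,
                               IntegerVector out_dims, bool nearest) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ox = out_dims[0], oy = out_dims[1], oz = out_dims[2];
  const double* V = REAL(vol);
  NumericVector out((R_xlen_t)ox * oy * oz);
  double* O = REAL(out);

  // output voxel t (1..N) center maps to input coordinate
  // lo - 0.5 + (t - 0.5) * (hi - lo + 1)/N   (box edges at lo-0.5, hi+0.5)
  auto coord = [](double l, double h, int N, int t) {
    return l - 0.5 + (t + 0.5) * (h - l + 1.0) / N;
  };
  auto clampi = [](int v, int n) { return v < 0 ? 0 : (v >= n ? n - 1 : v); };

  for (int kz = 0; kz < oz; ++kz) {
    const double z = coord(lo[2], hi[2], oz, kz) - 1.0;  // 0-based
    for (int ky = 0; ky < oy; ++ky) {
      const double y = coord(lo[1], hi[1], oy, ky) - 1.0;
      for (int kx = 0; kx < ox; ++kx) {
        const double x = coord(lo[0], hi[0], ox, kx) - 1.0;
        double val;
        if (nearest) {
          const int ix = clampi((int)std::lround(x), nx);
          const int iy = clampi((int)std::lround(y), ny);
          const int iz = clampi((int)std::lround(z), nz);
          val = V[ix + (R_xlen_t)nx * iy + (R_xlen_t)nx * ny * iz];
        } else {
          int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
              z0 = (int)std::floor(z);
          const double fx = x - x0, fy = y - y0, fz = z - z0;
          const int x0c = clampi(x0, nx), x1c = clampi(x0 + 1, nx);
          const int y0c = clampi(y0, ny), y1c = clampi(y0 + 1, ny);
          const int z0c = clampi(z0, nz), z1c = clampi(z0 + 1, nz);
          auto at = [&](int i, int j, int k) {
            return V[i + (R_xlen_t)nx * j + (R_xlen_t)nx * ny * k];
          };
          val =
            (1 - fz) * ((1 - fy) * ((1 - fx) * at(x0c, y0c, z0c) +
                                    fx * at(x1c, y0c, z0c)) +
                        fy * ((1 - fx) * at(x0c, y1c, z0c) +
                              fx * at(x1c, y1c, z0c))) +
            fz * ((1 - fy) * ((1 - fx) * at(x0c, y0c, z1c) +
                              fx * at(x1c, y0c, z1c)) +
                  fy * ((1 - fx) * at(x0c, y1c, z1c) +
                        fx * at(x1c, y1c, z1c)));
        }
        O[kx + (R_xlen_t)ox * ky + (R_xlen_t)ox * oy * kz] = val;
      }
    }
  }
  out.attr("dim") = out_dims;
  return out;
}
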