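// Voxel-driven FDK backprojection with bilinear detector interpolation.
// Filtered projections are given on the virtual detector at the isocenter
// plane (u along (-sin b, cos b, 0), v along +z), one slice per angle.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector fdk_backproject_cpp(NumericVector filt, IntegerVector pdims,
                                  NumericVector angles_deg, double sid,
                                  double du, double dv,
                                  IntegerVector vdims,
                                  NumericVector pitch_cm,
                                  double scale) {
  const int nu = pdims[0], nv = pdims[1], na = pdims[2];
  const int nx = vdims[0], ny = vdims[1], nz = vdims[2];
  const double px = pitch_cm[0], py = pitch_cm[1], pz = pitch_cm[2];
  const double cu = 0.5 * (nu - 1), cv = 0.5 * (nv - 1);
  NumericVector out((R_xlen_t)nx * ny * nz);
  const double* P = REAL(filt);
  double* V = REAL(out);

  for (int ia = 0; ia < na; ++ia) {
    const double b = angles_deg[ia] * M_PI / 180.0;
    const double cb = std::cos(b), sb = std::sin(b);
    const double* Pa = P + (R_xlen_t)nu * nv * ia;
    for (int iz = 0; iz < nz; ++iz) {
      const double z = (iz + 0.5 - 0.5 * nz) * pz;
      for (int iy = 0; iy < ny; ++iy) {
        const double y = (iy + 0.5 - 0.5 * ny) * py;
        for (int ix = 0; ix < nx; ++ix) {
          const double x = (ix + 0.5 - 0.5 * nx) * px;
          const double s = sid - (x * cb + y * sb);
          if (s <= 1e-6) continue;
          const double t = -x * sb + y * cb;
          const double ui = sid * t / s / du + cu;
          const double vi = sid * z / s / dv + cv;
          if (ui < 0 || ui > nu - 1 || vi < 0 || vi > nv - 1) continue;
          int u0 = (int)std::floor(ui), v0 = (int)std::floor(vi);
          if (u0 == nu - 1) u0--;
          if (v0 == nv - 1) v0--;
          const double fu = ui - u0, fv = vi - v0;
          const double p00 = Pa[u0 + (R_xlen_t)nu * v0];
          const double p10 = Pa[u0 + 1 + (R_xlen_t)nu * v0];
          const double p01 = Pa[u0 + (R_xlen_t)nu * (v0 + 1)];
          const double p11 = Pa[u0 + 1 + (R_xlen_t)nu * (v0 + 1)];
          const double pv = (1 - fu) * (1 - fv) * p00 + fu * (1 - fv) * p10 +
                            (1 - fu) * fv * p01 + fu * fv * p11;
          const double w = (sid * sid) / (s * s);
          V[ix + (R_xlen_t)nx * iy + (R_xlen_t)nx * ny * iz] += scale * w * pv;
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }
  out.attr("dim") = IntegerVector::create(nx, ny, nz);
  return out;
}

// 3x3 median per axial (z) slice with edge replication.
// [[Rcpp::export]]
NumericVector median3x3_slice_cpp(NumericVector vol, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  const double* V = REAL(vol);
  double* O = REAL(out);
  double buf[9];
  for (int iz = 0; iz < nz; ++iz) {
    const double* S = V + (R_xlen_t)nx * ny * iz;
    double* T = O + (R_xlen_t)nx * ny * iz;
    for (int iy = 0; iy < ny; ++iy) {
      for (int ix = 0; ix < nx; ++ix) {
        int n = 0;
        for (int dy = -1; dy <= 1; ++dy) {
          int jy = iy + dy;
          if (jy < 0) jy = 0; if (jy >= ny) jy = ny - 1;
          for (int dx = -1; dx <= 1; ++dx) {
            int jx = ix + dx;
            if (jx < 0) jx = 0; if (jx >= nx) jx = nx - 1;
            buf[n++] = S[jx + (R_xlen_t)nx * jy];
          }
        }
        std::nth_element(buf, buf + 4, buf + 9);
        T[ix + (R_xlen_t)nx * iy] = buf[4];
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// 3x3x3 median with edge replication (optional 3-D variant).
// [[Rcpp::export]]
NumericVector median3x3x3_cpp(NumericVector vol, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  const double* V = REAL(vol);
  double* O = REAL(out);
  double buf[27];
  for (int iz = 0; iz < nz; ++iz) {
    for (int iy = 0; iy < ny; ++iy) {
      for (int ix = 0; ix < nx; ++ix) {
        int n = 0;
        for (int dz = -1; dz <= 1; ++dz) {
          int jz = iz + dz;
          if (jz < 0) jz = 0; if (jz >= nz) jz = nz - 1;
          for (int dy = -1; dy <= 1; ++dy) {
            int jy = iy + dy;
            if (jy < 0) jy = 0; if (jy >= ny) jy = ny - 1;
            for (int dx = -1; dx <= 1; ++dx) {
              int jx = ix + dx;
              if (jx < 0) jx = 0; if (jx >= nx) jx = nx - 1;
              buf[n++] = V[jx + (R_xlen_t)nx * jy + (R_xlen_t)nx * ny * jz];
            }
          }
        }
        std::nth_element(buf, buf + 13, buf + 27);
        O[ix + (R_xlen_t)nx * iy + (R_xlen_t)nx * ny * iz] = buf[13];
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}
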