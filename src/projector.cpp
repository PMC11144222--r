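// Cone-beam geometry and polychromatic forward projection.
//
// Rays are cast from the source point to each detector pixel center and
// traversed through the voxel grid with an incremental parametric (Siddon
// style) algorithm giving exact per-voxel intersection lengths.  Because
// attenuation is material-based, each ray accumulates a path length per
// material row; the polychromatic intensity ratio is then the
// spectrum-weighted mean of exp(-sum_m t_m mu_m(E)) over the energy bins.
//
// Conventions: lengths in cm; the volume is centered on the isocenter with
// the rotation axis along +z; projection k views from angle k*step, counter-
// clockwise about +z, angle 0 putting the source on the +x axis.  Detector
// u runs along (-sin b, cos b, 0), v along +z.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct Grid {
  int nx, ny, nz;
  double px, py, pz;
  double x0, y0, z0;
};

// Parametric traversal from S to P; visit(ix, iy, iz, length_cm) is called
// for every voxel the segment crosses, in order from S to P.
template <typename F>
static void traverse(const Grid& g, double sx, double sy, double sz,
                     double ex, double ey, double ez, F&& visit) {
  const double dx = ex - sx, dy = ey - sy, dz = ez - sz;
  const double L = std::sqrt(dx * dx + dy * dy + dz * dz);
  if (L <= 0) return;
  double amin = 0.0, amax = 1.0;
  const double lox = g.x0, hix = g.x0 + g.nx * g.px;
  const double loy = g.y0, hiy = g.y0 + g.ny * g.py;
  const double loz = g.z0, hiz = g.z0 + g.nz * g.pz;
  auto clip = [&](double s, double d, double lo, double hi) {
    if (std::fabs(d) < 1e-14) {
      if (s < lo || s > hi) { amin = 1.0; amax = 0.0; }
      return;
    }
    double a1 = (lo - s) / d, a2 = (hi - s) / d;
    if (a1 > a2) std::swap(a1, a2);
    if (a1 > amin) amin = a1;
    if (a2 < amax) amax = a2;
  };
  clip(sx, dx, lox, hix);
  clip(sy, dy, loy, hiy);
  clip(sz, dz, loz, hiz);
  if (amin >= amax) return;

  // initial voxel: nudge just inside the entry face
  const double anudge = amin + (amax - amin) * 1e-10;
  int ix = (int)std::floor((sx + anudge * dx - g.x0) / g.px);
  int iy = (int)std::floor((sy + anudge * dy - g.y0) / g.py);
  int iz = (int)std::floor((sz + anudge * dz - g.z0) / g.pz);
  if (ix < 0) ix = 0; if (ix >= g.nx) ix = g.nx - 1;
  if (iy < 0) iy = 0; if (iy >= g.ny) iy = g.ny - 1;
  if (iz < 0) iz = 0; if (iz >= g.nz) iz = g.nz - 1;

  const double inf = std::numeric_limits<double>::infinity();
  int stx = dx > 0 ? 1 : -1, sty = dy > 0 ? 1 : -1, stz = dz > 0 ? 1 : -1;
  double dax = std::fabs(dx) > 1e-14 ? g.px / std::fabs(dx) : inf;
  double day = std::fabs(dy) > 1e-14 ? g.py / std::fabs(dy) : inf;
  double daz = std::fabs(dz) > 1e-14 ? g.pz / std::fabs(dz) : inf;
  auto next_cross = [&](double s, double d, double lo, double p,
                        int i) -> double {
    if (std::fabs(d) < 1e-14) return inf;
    double plane = d > 0 ? lo + (i + 1) * p : lo + i * p;
    return (plane - s) / d;
  };
  double ax = next_cross(sx, dx, g.x0, g.px, ix);
  double ay = next_cross(sy, dy, g.y0, g.py, iy);
  double az = next_cross(sz, dz, g.z0, g.pz, iz);

  double a = amin;
  while (true) {
    double anext = std::min(std::min(ax, ay), std::min(az, amax));
    double seg = (anext - a) * L;
    if (seg > 0) visit(ix, iy, iz, seg);
    if (anext >= amax - 1e-14) break;
    if (ax <= ay && ax <= az) { ix += stx; ax += dax; }
    else if (ay <= az)        { iy += sty; ay += day; }
    else                      { iz += stz; az += daz; }
    if (ix < 0 || ix >= g.nx || iy < 0 || iy >= g.ny ||
        iz < 0 || iz >= g.nz) break;
    a = anext;
  }
}

static Grid make_grid(const IntegerVector& dims, const NumericVector& pitch) {
  Grid g;
  g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2];
  g.px = pitch[0]; g.py = pitch[1]; g.pz = pitch[2];
  g.x0 = -0.5 * g.nx * g.px;
  g.y0 = -0.5 * g.ny * g.py;
  g.z0 = -0.5 * g.nz * g.pz;
  return g;
}

struct Ray {
  double sx, sy, sz, ex, ey, ez;
};

// source and pixel-center positions for detector pixel (iu, iv), 0-based
static Ray make_ray(double beta_deg, double sid, double sdd,
                    int ncols, int nrows, double du, double dv,
                    double iu, double iv) {
  const double b = beta_deg * M_PI / 180.0;
  const double cb = std::cos(b), sb = std::sin(b);
  Ray r;
  r.sx = sid * cb; r.sy = sid * sb; r.sz = 0.0;
  const double u = (iu - 0.5 * (ncols - 1)) * du;
  const double v = (iv - 0.5 * (nrows - 1)) * dv;
  // detector center = S - sdd*(cb, sb, 0); u axis = (-sb, cb, 0); v = +z
  r.ex = r.sx - sdd * cb - u * sb;
  r.ey = r.sy - sdd * sb + u * cb;
  r.ez = v;
  return r;
}

// [[Rcpp::export]]
List trace_ray_cpp(IntegerVector dims, NumericVector pitch_cm,
                   double beta_deg, double sid, double sdd,
                   int ncols, int nrows, double du, double dv,
                   double iu, double iv) {
  Grid g = make_grid(dims, pitch_cm);
  Ray r = make_ray(beta_deg, sid, sdd, ncols, nrows, du, dv, iu, iv);
  std::vector<int> vi, vj, vk;
  std::vector<double> len;
  traverse(g, r.sx, r.sy, r.sz, r.ex, r.ey, r.ez,
           [&](int ix, int iy, int iz, double L) {
             vi.push_back(ix + 1); vj.push_back(iy + 1); vk.push_back(iz + 1);
             len.push_back(L);
           });
  return List::create(_["i"] = wrap(vi), _["j"] = wrap(vj),
                      _["k"] = wrap(vk), _["length_cm"] = wrap(len));
}

// [[Rcpp::export]]
NumericVector forward_project_cpp(IntegerVector labels, IntegerVector dims,
                                  NumericVector pitch_cm,
                                  IntegerVector mat_lut, NumericMatrix mu,
                                  NumericVector weights,
                                  double sid, double sdd,
                                  int ncols, int nrows, double du, double dv,
                                  NumericVector angles_deg) {
  Grid g = make_grid(dims, pitch_cm);
  const int na = angles_deg.size();
  const int nmat = mu.nrow(), ne = mu.ncol();
  const double wsum = std::accumulate(weights.begin(), weights.end(), 0.0);
  NumericVector out((R_xlen_t)ncols * nrows * na);
  std::vector<double> tpath(nmat);
  const int* lab = INTEGER(labels);
  const R_xlen_t nxy = (R_xlen_t)g.nx * g.ny;

  for (int ia = 0; ia < na; ++ia) {
    const double beta = angles_deg[ia];
    for (int iv = 0; iv < nrows; ++iv) {
      for (int iu = 0; iu < ncols; ++iu) {
        Ray r = make_ray(beta, sid, sdd, ncols, nrows, du, dv, iu, iv);
        std::fill(tpath.begin(), tpath.end(), 0.0);
        traverse(g, r.sx, r.sy, r.sz, r.ex, r.ey, r.ez,
                 [&](int ix, int iy, int iz, double L) {
                   int m = mat_lut[lab[ix + (R_xlen_t)g.nx * iy + nxy * iz]];
                   if (m >= 0) tpath[m] += L;
                 });
        double acc = 0.0;
        for (int e = 0; e < ne; ++e) {
          double s = 0.0;
          for (int m = 0; m < nmat; ++m) {
            if (tpath[m] > 0.0) s += tpath[m] * mu(m, e);
          }
          acc += weights[e] * std::exp(-s);
        }
        double ratio = acc / wsum;
        if (!std::isfinite(ratio)) {
          stop("non-finite intensity ratio at angle %f, pixel (%d, %d)",
               beta, iu + 1, iv + 1);
        }
        out[iu + (R_xlen_t)ncols * iv + (R_xlen_t)ncols * nrows * ia] = ratio;
      }
    }
    Rcpp::checkUserInterrupt();
  }
  out.attr("dim") = IntegerVector::create(ncols, nrows, na);
  return out;
}
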