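// Angular-mean attenuation factor map by fixed-step ray marching.
// For every voxel centre, the full line integral of mu along an in-plane
// (transaxial) direction is accumulated in both directions — as for a
// coincidence line of response — and exp(-integral) is averaged over
// n_angles equally spaced directions in [0, pi).
// Physical coordinate of voxel index i (0-based) is i * spacing. Samples
// sit at t = (s + 0.5) * step from the voxel centre; interpolation is
// bilinear within the voxel's transaxial slice (rays are in-plane) and
// zero outside the grid. The marching range is clipped to the segment
// where the interpolant can be non-zero, which leaves the sum unchanged.
#include <Rcpp.h>
using namespace Rcpp;

static inline double bilin(const double* sl, int nx, int ny,
                           double qx, double qy) {
  if (qx <= -1.0 || qy <= -1.0 || qx >= nx || qy >= ny) return 0.0;
  int ix = (int)std::floor(qx), iy = (int)std::floor(qy);
  double wx = qx - ix, wy = qy - iy;
  if (ix >= 0 && ix < nx - 1 && iy >= 0 && iy < ny - 1) {
    const double* p = sl + (R_xlen_t)iy * nx + ix;
    return (1 - wy) * ((1 - wx) * p[0] + wx * p[1]) +
           wy * ((1 - wx) * p[nx] + wx * p[nx + 1]);
  }
  double v00 = 0, v10 = 0, v01 = 0, v11 = 0;
  bool x0 = ix >= 0 && ix < nx, x1 = ix + 1 >= 0 && ix + 1 < nx;
  bool y0 = iy >= 0 && iy < ny, y1 = iy + 1 >= 0 && iy + 1 < ny;
  if (x0 && y0) v00 = sl[(R_xlen_t)iy * nx + ix];
  if (x1 && y0) v10 = sl[(R_xlen_t)iy * nx + ix + 1];
  if (x0 && y1) v01 = sl[((R_xlen_t)iy + 1) * nx + ix];
  if (x1 && y1) v11 = sl[((R_xlen_t)iy + 1) * nx + ix + 1];
  return (1 - wy) * ((1 - wx) * v00 + wx * v10) +
         wy * ((1 - wx) * v01 + wx * v11);
}

// clip parametric range [0, tmax] of x0 + t*c against slab [-1, n]
static inline bool clipAxis(double x0, double c, double n, double& tlo,
                            double& thi) {
  if (std::fabs(c) < 1e-12) return x0 > -1.0 && x0 < n;
  double t1 = (-1.0 - x0) / c, t2 = (n - x0) / c;
  if (t1 > t2) std::swap(t1, t2);
  if (t1 > tlo) tlo = t1;
  if (t2 < thi) thi = t2;
  return tlo <= thi;
}

// [[Rcpp::export(name = ".raymarchAF")]]
NumericVector raymarch_af(NumericVector mu, IntegerVector dims,
                          NumericVector spacing, int n_angles, double step) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1];
  const double ex = nx * sx, ey = ny * sy;  // in-plane physical extent (mm)
  const double diag = std::sqrt(ex * ex + ey * ey);
  const int nstep = (int)std::ceil(diag / step);
  const double* m = mu.begin();
  NumericVector af((R_xlen_t)nx * ny * nz);
  std::vector<double> cosv(n_angles), sinv(n_angles);
  for (int a = 0; a < n_angles; ++a) {
    double th = M_PI * a / n_angles;
    cosv[a] = std::cos(th);
    sinv[a] = std::sin(th);
  }
  for (int z = 0; z < nz; ++z) {
    const double* sl = m + (R_xlen_t)z * nx * ny;
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        double acc = 0.0;
        for (int a = 0; a < n_angles; ++a) {
          // direction in index units per mm of ray parameter
          const double cx = cosv[a] / sx, cy = sinv[a] / sy;
          double L = 0.0;
          for (int sgn = -1; sgn <= 1; sgn += 2) {
            const double dx = sgn * cx, dy = sgn * cy;
            double tlo = 0.0, thi = nstep * step;
            if (!clipAxis((double)x, dx, (double)nx, tlo, thi)) continue;
            if (!clipAxis((double)y, dy, (double)ny, tlo, thi)) continue;
            int s0 = (int)std::floor(tlo / step - 0.5);
            if (s0 < 0) s0 = 0;
            int s1 = (int)std::ceil(thi / step - 0.5);
            if (s1 > nstep - 1) s1 = nstep - 1;
            for (int s = s0; s <= s1; ++s) {
              const double t = (s + 0.5) * step;
              L += bilin(sl, nx, ny, x + t * dx, y + t * dy);
            }
          }
          acc += std::exp(-L * step);
        }
        af[((R_xlen_t)z * ny + y) * nx + x] = acc / n_angles;
      }
    }
  }
  af.attr("dim") = IntegerVector::create(nx, ny, nz);
  return af;
}
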