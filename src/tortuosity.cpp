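#include <Rcpp.h>
#include "rng.h"
using namespace Rcpp;

// Periodic cuboid lattice with dead-end cavities: a cubic cell of edge
// `cube` sits in each period `pitch = cube + gap`, carrying a square cavity
// (side `cav_w`, depth `cav_d`) that opens on its +z face.  All lengths nm.
// A point is solid if it lies inside the cube but outside the cavity.
static inline bool is_solid(double x, double y, double z,
                            double pitch, double g2, double cube,
                            double cav_lo, double cav_hi, double cav_zlo) {
  double ux = x - pitch * std::floor(x / pitch);
  double uy = y - pitch * std::floor(y / pitch);
  double uz = z - pitch * std::floor(z / pitch);
  if (ux < g2 || ux >= g2 + cube || uy < g2 || uy >= g2 + cube ||
      uz < g2 || uz >= g2 + cube)
    return false;
  if (ux >= cav_lo && ux < cav_hi && uy >= cav_lo && uy < cav_hi &&
      uz >= cav_zlo)
    return false;  // inside the cavity: extracellular
  return true;
}

// Random-walk estimate of the MSD curve inside the lattice extracellular
// space.  Walkers start at equilibrium (uniform over the extracellular
// volume) and take axis-aligned steps of length `h`, rejected when the
// destination is solid.  Returns per-checkpoint step counts and MSD (nm^2).
// [[Rcpp::export]]
List walk_lattice_msd(int n_walkers, int n_steps, double h,
                      double cube, double gap, double cav_w, double cav_d,
                      int n_checkpoints, int seed, bool free_space) {
  double pitch = cube + gap, g2 = gap / 2.0;
  double cav_lo = g2 + (cube - cav_w) / 2.0;
  double cav_hi = cav_lo + cav_w;
  double cav_zlo = g2 + cube - cav_d;
  XRng rng((uint64_t)seed);

  std::vector<double> x(n_walkers), y(n_walkers), z(n_walkers);
  std::vector<double> x0(n_walkers), y0(n_walkers), z0(n_walkers);
  for (int i = 0; i < n_walkers; ++i) {
    double px, py, pz;
    do {
      px = rng.unif() * pitch;
      py = rng.unif() * pitch;
      pz = rng.unif() * pitch;
    } while (!free_space &&
             is_solid(px, py, pz, pitch, g2, cube, cav_lo, cav_hi, cav_zlo));
    x[i] = x0[i] = px; y[i] = y0[i] = py; z[i] = z0[i] = pz;
  }

  IntegerVector cp_steps(n_checkpoints);
  NumericVector cp_msd(n_checkpoints);
  int stride = n_steps / n_checkpoints;
  int cp = 0;
  for (int s = 1; s <= n_steps; ++s) {
    for (int i = 0; i < n_walkers; ++i) {
      uint64_t r = rng.next();
      int axis = (int)(r % 6);
      double d = (axis & 1) ? h : -h;
      double nx = x[i], ny = y[i], nz = z[i];
      if (axis < 2) nx += d; else if (axis < 4) ny += d; else nz += d;
      if (free_space ||
          !is_solid(nx, ny, nz, pitch, g2, cube, cav_lo, cav_hi, cav_zlo)) {
        x[i] = nx; y[i] = ny; z[i] = nz;
      }
    }
    if (s % stride == 0 && cp < n_checkpoints) {
      double acc = 0.0;
      for (int i = 0; i < n_walkers; ++i) {
        double dx = x[i] - x0[i], dy = y[i] - y0[i], dz = z[i] - z0[i];
        acc += dx * dx + dy * dy + dz * dz;
      }
      cp_steps[cp] = s;
      cp_msd[cp] = acc / n_walkers;
      ++cp;
    }
  }
  return List::create(_["steps"] = cp_steps, _["msd"] = cp_msd);
}
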