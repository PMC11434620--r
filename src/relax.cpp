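#include <Rcpp.h>
using namespace Rcpp;

// Overlap-removal relaxation for the bead chain.
//
// Energy model: harmonic half-spring repulsion k_rep*(2r - d)^2 between
// any pair with d < 2r (bonded included), harmonic bonds
// k_bond*(d - rest)^2 along the chain.  Integrator: damped inertial
// descent (FIRE-style): velocities are mixed toward the force direction
// while the power F.v stays positive and the timestep grows; on negative
// power the velocities reset and the timestep shrinks.  When
// temperature = 0 any step that raises the energy is reverted, so the
// accepted-energy sequence is non-increasing.  Optional thermal noise
// (temperature > 0, nm amplitude) uses R's RNG.  Beads leaving the
// confinement sphere of radius rc about com0 are reflected.  Terminates
// as soon as no non-bonded pair is closer than 2r*(1 - overlap_tol).

namespace {

struct CellList {
  double h, x0, y0, z0;
  int nx, ny, nz;
  std::vector<int> head, nxt;

  void build(const std::vector<double>& x, const std::vector<double>& y,
             const std::vector<double>& z, double cell) {
    const int n = (int)x.size();
    h = cell;
    double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0],
           zmin = z[0], zmax = z[0];
    for (int i = 1; i < n; ++i) {
      xmin = std::min(xmin, x[i]); xmax = std::max(xmax, x[i]);
      ymin = std::min(ymin, y[i]); ymax = std::max(ymax, y[i]);
      zmin = std::min(zmin, z[i]); zmax = std::max(zmax, z[i]);
    }
    x0 = xmin - h; y0 = ymin - h; z0 = zmin - h;
    nx = (int)((xmax - x0) / h) + 2;
    ny = (int)((ymax - y0) / h) + 2;
    nz = (int)((zmax - z0) / h) + 2;
    head.assign((size_t)nx * ny * nz, -1);
    nxt.assign(n, -1);
    for (int i = 0; i < n; ++i) {
      const int c = cell_of(x[i], y[i], z[i]);
      nxt[i] = head[c];
      head[c] = i;
    }
  }

  inline int cell_of(double xi, double yi, double zi) const {
    int cx = (int)((xi - x0) / h), cy = (int)((yi - y0) / h),
        cz = (int)((zi - z0) / h);
    cx = std::max(0, std::min(cx, nx - 1));
    cy = std::max(0, std::min(cy, ny - 1));
    cz = std::max(0, std::min(cz, nz - 1));
    return (cz * ny + cy) * nx + cx;
  }
};

}  // namespace

// [[Rcpp::export]]
List relax_cpp(NumericMatrix pos0, double bead_radius, NumericVector rest_len,
               double overlap_tol, int max_steps, double k_rep, double k_bond,
               double step_scale, double max_disp, double temperature,
               double rc, NumericVector com0) {
  const int n = pos0.nrow();
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pos0(i, 0); y[i] = pos0(i, 1); z[i] = pos0(i, 2);
  }
  std::vector<double> xp = x, yp = y, zp = z;  // last accepted
  std::vector<double> fx(n), fy(n), fz(n);
  std::vector<double> vx(n, 0.0), vy(n, 0.0), vz(n, 0.0);

  const double d0 = 2.0 * bead_radius;           // contact distance
  const double dmin = d0 * (1.0 - overlap_tol);  // termination threshold
  // repulsion keeps acting slightly beyond contact so that force-balanced
  // minima sit above the termination threshold, not below it
  const double d0r = d0 * (1.0 + 3.0 * overlap_tol);
  const double d02 = d0r * d0r;
  CellList cl;
  std::vector<double> energies;
  energies.reserve(std::min(max_steps, 100000));

  // FIRE parameters; `step_scale` is the initial timestep, capped at
  // 4x that value.
  double dt = step_scale;
  const double dt_max = 4.0 * step_scale, dt_min = 1e-6 * step_scale;
  const double a_start = 0.25;
  double a_mix = a_start;
  double e_prev = R_PosInf;
  int iter = 0, n_overlap = -1, stall = 0;
  bool converged = false;

  for (iter = 0; iter < max_steps; ++iter) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    double energy = 0.0;
    n_overlap = 0;

    cl.build(x, y, z, d0r);
    for (int i = 0; i < n; ++i) {
      const int cx = (int)((x[i] - cl.x0) / cl.h);
      const int cy = (int)((y[i] - cl.y0) / cl.h);
      const int cz = (int)((z[i] - cl.z0) / cl.h);
      for (int az = std::max(0, cz - 1); az <= std::min(cl.nz - 1, cz + 1); ++az)
        for (int ay = std::max(0, cy - 1); ay <= std::min(cl.ny - 1, cy + 1); ++ay)
          for (int ax = std::max(0, cx - 1); ax <= std::min(cl.nx - 1, cx + 1); ++ax) {
            int j = cl.head[((size_t)az * cl.ny + ay) * cl.nx + ax];
            for (; j >= 0; j = cl.nxt[j]) {
              // repulsion acts between ALL bead pairs, bonded included;
              // only non-bonded pairs count toward the overlap criterion
              if (j <= i) continue;
              const double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
              const double r2 = dx * dx + dy * dy + dz * dz;
              if (r2 >= d02) continue;
              const double d = std::sqrt(r2);
              if (d < dmin && j - i > 1) ++n_overlap;
              const double pen = d0r - d;
              energy += k_rep * pen * pen;
              // push apart; guard near-coincident pairs
              const double inv = (d > 1e-9) ? 1.0 / d : 0.0;
              const double f = 2.0 * k_rep * pen * inv;
              fx[i] += f * dx; fy[i] += f * dy; fz[i] += f * dz;
              fx[j] -= f * dx; fy[j] -= f * dy; fz[j] -= f * dz;
            }
          }
    }
    // bonds
    for (int i = 0; i + 1 < n; ++i) {
      const double dx = x[i + 1] - x[i], dy = y[i + 1] - y[i],
                   dz = z[i + 1] - z[i];
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      const double dev = d - rest_len[i];
      energy += k_bond * dev * dev;
      const double inv = (d > 1e-9) ? 1.0 / d : 0.0;
      const double f = -2.0 * k_bond * dev * inv;
      fx[i + 1] += f * dx; fy[i + 1] += f * dy; fz[i + 1] += f * dz;
      fx[i] -= f * dx; fy[i] -= f * dy; fz[i] -= f * dz;
    }

    if (n_overlap == 0) { converged = true; energies.push_back(energy); break; }

    if (temperature <= 0.0 && energy > e_prev) {
      // uphill: revert to last accepted configuration, kill the inertia
      x = xp; y = yp; z = zp;
      std::fill(vx.begin(), vx.end(), 0.0);
      std::fill(vy.begin(), vy.end(), 0.0);
      std::fill(vz.begin(), vz.end(), 0.0);
      dt = std::max(dt * 0.5, dt_min);
      a_mix = a_start;
      continue;
    }
    // bail out if the descent has frozen (no meaningful energy change)
    if (e_prev - energy <= 1e-12 * std::max(energy, 1.0)) {
      if (++stall > 2000) { energies.push_back(energy); break; }
    } else {
      stall = 0;
    }
    energies.push_back(energy);
    e_prev = energy;
    xp = x; yp = y; zp = z;

    // FIRE velocity mixing on the power sign
    double power = 0.0, vnorm2 = 0.0, fnorm2 = 0.0;
    for (int i = 0; i < n; ++i) {
      power += vx[i] * fx[i] + vy[i] * fy[i] + vz[i] * fz[i];
      vnorm2 += vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i];
      fnorm2 += fx[i] * fx[i] + fy[i] * fy[i] + fz[i] * fz[i];
    }
    if (power > 0.0) {
      const double mix = (fnorm2 > 0.0)
        ? a_mix * std::sqrt(vnorm2 / fnorm2) : 0.0;
      for (int i = 0; i < n; ++i) {
        vx[i] = (1.0 - a_mix) * vx[i] + mix * fx[i];
        vy[i] = (1.0 - a_mix) * vy[i] + mix * fy[i];
        vz[i] = (1.0 - a_mix) * vz[i] + mix * fz[i];
      }
      dt = std::min(dt * 1.1, dt_max);
      a_mix *= 0.99;
    } else {
      std::fill(vx.begin(), vx.end(), 0.0);
      std::fill(vy.begin(), vy.end(), 0.0);
      std::fill(vz.begin(), vz.end(), 0.0);
      dt = std::max(dt * 0.5, dt_min);
      a_mix = a_start;
    }

    for (int i = 0; i < n; ++i) {
      vx[i] += dt * fx[i];
      vy[i] += dt * fy[i];
      vz[i] += dt * fz[i];
      double ddx = dt * vx[i], ddy = dt * vy[i], ddz = dt * vz[i];
      if (temperature > 0.0) {
        ddx += temperature * norm_rand();
        ddy += temperature * norm_rand();
        ddz += temperature * norm_rand();
      }
      const double dd = std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz);
      if (dd > max_disp) {
        const double s = max_disp / dd;
        ddx *= s; ddy *= s; ddz *= s;
      }
      x[i] += ddx; y[i] += ddy; z[i] += ddz;
      // reflecting confinement about com0
      const double ex = x[i] - com0[0], ey = y[i] - com0[1],
                   ez = z[i] - com0[2];
      const double r = std::sqrt(ex * ex + ey * ey + ez * ez);
      if (r > rc) {
        const double rnew = std::max(2.0 * rc - r, 0.0);
        const double s = (r > 1e-12) ? rnew / r : 0.0;
        x[i] = com0[0] + ex * s;
        y[i] = com0[1] + ey * s;
        z[i] = com0[2] + ez * s;
      }
    }
  }

  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = x[i]; out(i, 1) = y[i]; out(i, 2) = z[i];
  }
  return List::create(_["positions"] = out,
                      _["converged"] = converged,
                      _["iterations"] = iter,
                      _["residual_overlaps"] = n_overlap,
                      _["energy"] = NumericVector(energies.begin(),
                                                  energies.end()));
}

// Count non-bonded pairs closer than 2*bead_radius*(1 - tol), cell list.
// [[Rcpp::export]]
int count_overlaps_grid_cpp(NumericMatrix pos, double bead_radius,
                            double tol) {
  const int n = pos.nrow();
  if (n < 3) {
    if (n < 2) return 0;
  }
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2);
  }
  const double thr = 2.0 * bead_radius * (1.0 - tol);
  const double thr2 = thr * thr;
  CellList cl;
  cl.build(x, y, z, 2.0 * bead_radius);
  int count = 0;
  for (int i = 0; i < n; ++i) {
    const int cx = (int)((x[i] - cl.x0) / cl.h);
    const int cy = (int)((y[i] - cl.y0) / cl.h);
    const int cz = (int)((z[i] - cl.z0) / cl.h);
    for (int az = std::max(0, cz - 1); az <= std::min(cl.nz - 1, cz + 1); ++az)
      for (int ay = std::max(0, cy - 1); ay <= std::min(cl.ny - 1, cy + 1); ++ay)
        for (int ax = std::max(0, cx - 1); ax <= std::min(cl.nx - 1, cx + 1); ++ax) {
          int j = cl.head[((size_t)az * cl.ny + ay) * cl.nx + ax];
          for (; j >= 0; j = cl.nxt[j]) {
            if (j <= i || std::abs(j - i) == 1) continue;
            const double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
            if (dx * dx + dy * dy + dz * dz < thr2) ++count;
          }
        }
  }
  return count;
}
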