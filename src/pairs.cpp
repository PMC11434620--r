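#include <Rcpp.h>
using namespace Rcpp;

// Cell-list pair analysis: radial pair histogram for g(r), per-bead
// coordination numbers, seeded pair sampling for end-to-end / contact
// curves, and exact bead-sphere/probe-sphere intersection volume.

namespace {

struct Grid {
  double h, x0, y0, z0;
  int nx, ny, nz;
  std::vector<int> head, nxt;

  void build(const NumericMatrix& p, double cell) {
    const int n = p.nrow();
    h = cell;
    double xmin = p(0, 0), xmax = p(0, 0), ymin = p(0, 1), ymax = p(0, 1),
           zmin = p(0, 2), zmax = p(0, 2);
    for (int i = 1; i < n; ++i) {
      xmin = std::min(xmin, p(i, 0)); xmax = std::max(xmax, p(i, 0));
      ymin = std::min(ymin, p(i, 1)); ymax = std::max(ymax, p(i, 1));
      zmin = std::min(zmin, p(i, 2)); zmax = std::max(zmax, p(i, 2));
    }
    x0 = xmin - h; y0 = ymin - h; z0 = zmin - h;
    nx = (int)((xmax - x0) / h) + 2;
    ny = (int)((ymax - y0) / h) + 2;
    nz = (int)((zmax - z0) / h) + 2;
    head.assign((size_t)nx * ny * nz, -1);
    nxt.assign(n, -1);
    for (int i = 0; i < n; ++i) {
      int cx = (int)((p(i, 0) - x0) / h), cy = (int)((p(i, 1) - y0) / h),
          cz = (int)((p(i, 2) - z0) / h);
      const int c = ((size_t)cz * ny + cy) * nx + cx;
      nxt[i] = head[c];
      head[c] = i;
    }
  }
};

}  // namespace

// Histogram of center-to-neighbor distances for the beads listed in
// centers (1-based), over all other beads, binned as floor(d / dr) up to
// r_max.  Used to form g(r).
// [[Rcpp::export]]
NumericVector pair_hist_cpp(NumericMatrix pos, IntegerVector centers,
                            double r_max, double dr) {
  const int nbins = (int)std::ceil(r_max / dr);
  NumericVector counts(nbins);
  const double h = r_max / 4.0;
  Grid g;
  g.build(pos, h);
  const double r_max2 = r_max * r_max;
  const int reach = 5;  // ceil(r_max / h) + 1
  for (int ci = 0; ci < centers.size(); ++ci) {
    const int i = centers[ci] - 1;
    const double xi = pos(i, 0), yi = pos(i, 1), zi = pos(i, 2);
    const int cx = (int)((xi - g.x0) / g.h), cy = (int)((yi - g.y0) / g.h),
              cz = (int)((zi - g.z0) / g.h);
    for (int az = std::max(0, cz - reach); az <= std::min(g.nz - 1, cz + reach); ++az)
      for (int ay = std::max(0, cy - reach); ay <= std::min(g.ny - 1, cy + reach); ++ay)
        for (int ax = std::max(0, cx - reach); ax <= std::min(g.nx - 1, cx + reach); ++ax) {
          int j = g.head[((size_t)az * g.ny + ay) * g.nx + ax];
          for (; j >= 0; j = g.nxt[j]) {
            if (j == i) continue;
            const double dx = xi - pos(j, 0), dy = yi - pos(j, 1),
                         dz = zi - pos(j, 2);
            const double d2 = dx * dx + dy * dy + dz * dz;
            if (d2 >= r_max2) continue;
            const int b = (int)(std::sqrt(d2) / dr);
            if (b < nbins) counts[b] += 1.0;
          }
        }
  }
  return counts;
}

// Number of other bead centers within `radius` of each bead.
// [[Rcpp::export]]
IntegerVector coord_number_cpp(NumericMatrix pos, double radius) {
  const int n = pos.nrow();
  IntegerVector cn(n);
  Grid g;
  g.build(pos, radius);
  const double r2 = radius * radius;
  for (int i = 0; i < n; ++i) {
    const double xi = pos(i, 0), yi = pos(i, 1), zi = pos(i, 2);
    const int cx = (int)((xi - g.x0) / g.h), cy = (int)((yi - g.y0) / g.h),
              cz = (int)((zi - g.z0) / g.h);
    int c = 0;
    for (int az = std::max(0, cz - 1); az <= std::min(g.nz - 1, cz + 1); ++az)
      for (int ay = std::max(0, cy - 1); ay <= std::min(g.ny - 1, cy + 1); ++ay)
        for (int ax = std::max(0, cx - 1); ax <= std::min(g.nx - 1, cx + 1); ++ax) {
          int j = g.head[((size_t)az * g.ny + ay) * g.nx + ax];
          for (; j >= 0; j = g.nxt[j]) {
            if (j == i) continue;
            const double dx = xi - pos(j, 0), dy = yi - pos(j, 1),
                         dz = zi - pos(j, 2);
            if (dx * dx + dy * dy + dz * dz <= r2) ++c;
          }
        }
    cn[i] = c;
  }
  return cn;
}

// For each bead separation s in seps, sample up to n_per_sep pairs
// (i, i+s) (all of them when fewer are available, random starts via R's
// RNG otherwise) and record genomic separation (bp), squared spatial
// distance and contact indicator (d < cutoff).
// [[Rcpp::export]]
NumericMatrix pair_samples_cpp(NumericMatrix pos, NumericVector cum_bp,
                               IntegerVector seps, int n_per_sep,
                               double cutoff) {
  const int n = pos.nrow();
  const double cut2 = cutoff * cutoff;
  int total = 0;
  for (int k = 0; k < seps.size(); ++k) {
    const int avail = n - seps[k];
    if (avail > 0) total += std::min(avail, n_per_sep);
  }
  NumericMatrix out(total, 3);
  int row = 0;
  for (int k = 0; k < seps.size(); ++k) {
    const int s = seps[k];
    const int avail = n - s;
    if (avail <= 0) continue;
    const int m = std::min(avail, n_per_sep);
    for (int t = 0; t < m; ++t) {
      const int i = (m == avail) ? t : (int)(unif_rand() * avail);
      const int j = i + s;
      const double dx = pos(i, 0) - pos(j, 0), dy = pos(i, 1) - pos(j, 1),
                   dz = pos(i, 2) - pos(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      out(row, 0) = std::abs(cum_bp[j] - cum_bp[i]);
      out(row, 1) = d2;
      out(row, 2) = (d2 < cut2) ? 1.0 : 0.0;
      ++row;
    }
  }
  return out;
}

// Total bead volume inside a probe sphere (center, R), exact
// sphere-sphere lens volume per bead of radius r0.
// [[Rcpp::export]]
double local_volume_cpp(NumericMatrix pos, NumericVector center, double R,
                        double r0) {
  const int n = pos.nrow();
  const double vfull = 4.0 / 3.0 * M_PI * r0 * r0 * r0;
  const double reach = R + r0;
  double v = 0.0;
  for (int i = 0; i < n; ++i) {
    const double dx = pos(i, 0) - center[0], dy = pos(i, 1) - center[1],
                 dz = pos(i, 2) - center[2];
    const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (d >= reach) continue;
    if (d <= R - r0) {
      v += vfull;
    } else {
      // lens: intersection of spheres radius r0 and R at distance d
      const double a = R + r0 - d;
      v += M_PI * a * a *
           (d * d + 2.0 * d * r0 - 3.0 * r0 * r0 + 2.0 * d * R +
            6.0 * r0 * R - 3.0 * R * R) / (12.0 * d);
    }
  }
  return v;
}
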