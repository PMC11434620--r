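#include <Rcpp.h>
using namespace Rcpp;

// Self-returning random walk generator.
//
// At each step the walk either retraces the last backbone segment (with
// probability U0^(-alpha)/alpha where U0 is the segment's length in units)
// or jumps in an isotropic random direction with a heavy-tailed length
// U ~ (alpha+1) U^(-alpha-2), U >= 1, truncated at local_cutoff.
// Jump candidates falling farther than rc from the center of mass of the
// already-generated vertices are rejected and resampled.  Consecutive
// returns pop successive backbone segments; at the origin (empty backbone)
// a jump is forced.
//
// Uses R's RNG so set.seed() governs reproducibility.

// [[Rcpp::export]]
List srrw_generate_cpp(double alpha, int n_beads, double rc,
                       double unit_length, double local_cutoff,
                       int max_attempts) {
  NumericMatrix pos(n_beads, 3);
  IntegerVector types(n_beads - 1);   // 1 = jump, 2 = return
  NumericVector lens(n_beads - 1);    // step length in units

  // backbone stack of step vectors (nm) and lengths (units)
  std::vector<double> sx, sy, sz, sl;
  sx.reserve(n_beads); sy.reserve(n_beads);
  sz.reserve(n_beads); sl.reserve(n_beads);

  double sumx = 0.0, sumy = 0.0, sumz = 0.0;  // running vertex sum for COM
  const double rc2 = rc * rc;
  const double inv_ap1 = -1.0 / (alpha + 1.0);

  for (int i = 1; i < n_beads; ++i) {
    const double comx = sumx / i, comy = sumy / i, comz = sumz / i;
    bool do_return = false;
    if (!sl.empty()) {
      const double u0 = sl.back();
      const double pr = std::pow(u0, -alpha) / alpha;
      do_return = (unif_rand() < pr);
    }
    if (do_return) {
      pos(i, 0) = pos(i - 1, 0) - sx.back();
      pos(i, 1) = pos(i - 1, 1) - sy.back();
      pos(i, 2) = pos(i - 1, 2) - sz.back();
      lens[i - 1] = sl.back();
      types[i - 1] = 2;
      sx.pop_back(); sy.pop_back(); sz.pop_back(); sl.pop_back();
    } else {
      int attempt = 0;
      double cx = 0, cy = 0, cz = 0, dx = 0, dy = 0, dz = 0, u = 0;
      for (;;) {
        if (++attempt > max_attempts)
          stop("failed to place vertex %d within the global cutoff after "
               "%d attempts", i + 1, max_attempts);
        u = std::pow(1.0 - unif_rand(), inv_ap1);
        if (u > local_cutoff) continue;
        const double z = 2.0 * unif_rand() - 1.0;
        const double th = 2.0 * M_PI * unif_rand();
        const double s = std::sqrt(1.0 - z * z);
        dx = s * std::cos(th) * u * unit_length;
        dy = s * std::sin(th) * u * unit_length;
        dz = z * u * unit_length;
        cx = pos(i - 1, 0) + dx;
        cy = pos(i - 1, 1) + dy;
        cz = pos(i - 1, 2) + dz;
        const double ex = cx - comx, ey = cy - comy, ez = cz - comz;
        if (ex * ex + ey * ey + ez * ez <= rc2) break;
      }
      pos(i, 0) = cx; pos(i, 1) = cy; pos(i, 2) = cz;
      sx.push_back(dx); sy.push_back(dy); sz.push_back(dz); sl.push_back(u);
      lens[i - 1] = u;
      types[i - 1] = 1;
    }
    sumx += pos(i, 0); sumy += pos(i, 1); sumz += pos(i, 2);
  }

  return List::create(_["vertices"] = pos,
                      _["step_types"] = types,
                      _["step_lengths"] = lens);
}
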