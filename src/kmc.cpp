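#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// One lattice move: pick one of the six axis directions with equal
// probability.  A move whose target site lies outside the box, or (when
// R2_confine > 0) whose centre lies outside the reflecting spherical
// membrane of squared radius R2_confine about ctr, is rejected and the
// walker stays in place for that step (lattice reflection).
static inline void step_once(int pos[3], const int n[3], const double unit[3],
                             const double ctr[3], double R2_confine,
                             double u) {
  int k = (int)(u * 6.0);
  if (k > 5) k = 5;
  int axis = k >> 1;
  int dir = (k & 1) ? 1 : -1;
  int np = pos[axis] + dir;
  if (np < 0 || np >= n[axis]) return;
  if (R2_confine > 0) {
    double d2 = 0.0;
    for (int a = 0; a < 3; ++a) {
      double c = ((a == axis ? np : pos[a]) - ctr[a]) * unit[a];
      d2 += c * c;
    }
    if (d2 > R2_confine) return;
  }
  pos[axis] = np;
}

static inline bool inside_nucleus(const int pos[3], const double unit[3],
                                  const double ctr[3], double ra, double ra2) {
  double dx = (pos[0] - ctr[0]) * unit[0];
  if (std::fabs(dx) > ra) return false;
  double dy = (pos[1] - ctr[1]) * unit[1];
  if (std::fabs(dy) > ra) return false;
  double dz = (pos[2] - ctr[2]) * unit[2];
  return dx * dx + dy * dy + dz * dz <= ra2;
}

// Run a single walker for at most max_steps steps.  Absorption test uses
// the Euclidean distance of the site centre to the nucleus centre.
// R_confine <= 0 disables the spherical membrane (box-only reflection).
// Uses R's RNG (seed with set.seed() before the call).
// [[Rcpp::export]]
List kmc_run_cpp(IntegerVector start, IntegerVector n_units,
                 NumericVector unit_um, NumericVector center,
                 double ra_um, double R_confine, double max_steps,
                 bool absorb) {
  int pos[3] = {start[0], start[1], start[2]};
  int n[3] = {n_units[0], n_units[1], n_units[2]};
  double unit[3] = {unit_um[0], unit_um[1], unit_um[2]};
  double ctr[3] = {center[0], center[1], center[2]};
  for (int a = 0; a < 3; ++a)
    if (pos[a] < 0 || pos[a] >= n[a])
      stop("walker initialised outside the box");
  double ra2 = ra_um * ra_um;
  double R2 = R_confine > 0 ? R_confine * R_confine : -1.0;
  double steps = 0.0;
  bool absorbed = absorb && inside_nucleus(pos, unit, ctr, ra_um, ra2);
  while (!absorbed && steps < max_steps) {
    step_once(pos, n, unit, ctr, R2, unif_rand());
    steps += 1.0;
    if (absorb && inside_nucleus(pos, unit, ctr, ra_um, ra2))
      absorbed = true;
  }
  return List::create(_["steps"] = steps, _["absorbed"] = absorbed,
                      _["pos"] = IntegerVector::create(pos[0], pos[1], pos[2]));
}

// Record the full path (positions after each step); shares the same move
// rule, used by the unit tests of the stepping contract.
// [[Rcpp::export]]
IntegerMatrix kmc_path_cpp(IntegerVector start, IntegerVector n_units,
                           NumericVector unit_um, NumericVector center,
                           double R_confine, int n_steps) {
  int pos[3] = {start[0], start[1], start[2]};
  int n[3] = {n_units[0], n_units[1], n_units[2]};
  double unit[3] = {unit_um[0], unit_um[1], unit_um[2]};
  double ctr[3] = {center[0], center[1], center[2]};
  double R2 = R_confine > 0 ? R_confine * R_confine : -1.0;
  IntegerMatrix out(n_steps, 3);
  for (int s = 0; s < n_steps; ++s) {
    step_once(pos, n, unit, ctr, R2, unif_rand());
    out(s, 0) = pos[0];
    out(s, 1) = pos[1];
    out(s, 2) = pos[2];
  }
  return out;
}
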