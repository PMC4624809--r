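#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama simulation of the two-boundary Wiener diffusion.
// Trial-level drift is N(v, sv^2), non-decision time uniform over
// [t0 - st/2, t0 + st/2]. Returns absorption times (including non-decision
// time) and which boundary was hit; trials not absorbed by max_t get NA.
// Uses R's RNG so results are reproducible under set.seed().

// [[Rcpp::export(name = ".ddm_sim_cpp")]]
List ddm_sim_cpp(int n, double v, double a, double z_rel, double t0,
                 double sv, double st, double dt, double max_t) {
  if (a <= 0.0) stop("boundary separation 'a' must be positive");
  if (dt <= 0.0) stop("'dt' must be positive");
  NumericVector rt(n);
  LogicalVector upper(n);
  double sdt = std::sqrt(dt);
  double z = z_rel * a;
  for (int i = 0; i < n; ++i) {
    double vi = sv > 0.0 ? R::rnorm(v, sv) : v;
    double t0i = st > 0.0 ? R::runif(t0 - st / 2.0, t0 + st / 2.0) : t0;
    double x = z, t = 0.0;
    int hit = -1;
    while (t < max_t) {
      x += vi * dt + sdt * R::norm_rand();
      t += dt;
      if (x >= a) { hit = 1; break; }
      if (x <= 0.0) { hit = 0; break; }
    }
    if (hit < 0) {
      rt[i] = NA_REAL;
      upper[i] = NA_LOGICAL;
    } else {
      rt[i] = t + t0i;
      upper[i] = hit == 1;
    }
  }
  return List::create(_["rt"] = rt, _["upper"] = upper);
}

// Accumulate until a boundary is hit or the response cue arrives at cue_t;
// if no boundary was reached, the choice is read off the sign of the
// accumulated evidence relative to the start point (ties -> coin flip).
// [[Rcpp::export(name = ".ddm_sim_until_cue_cpp")]]
List ddm_sim_until_cue_cpp(int n, double v, double a, double z_rel,
                           double sv, double dt, double cue_t) {
  if (a <= 0.0) stop("boundary separation 'a' must be positive");
  if (dt <= 0.0) stop("'dt' must be positive");
  if (cue_t <= 0.0) stop("'cue_t' must be positive");
  LogicalVector upper(n);
  LogicalVector boundary_hit(n);
  double sdt = std::sqrt(dt);
  double z = z_rel * a;
  for (int i = 0; i < n; ++i) {
    double vi = sv > 0.0 ? R::rnorm(v, sv) : v;
    double x = z, t = 0.0;
    int hit = -1;
    while (t < cue_t) {
      x += vi * dt + sdt * R::norm_rand();
      t += dt;
      if (x >= a) { hit = 1; break; }
      if (x <= 0.0) { hit = 0; break; }
    }
    if (hit >= 0) {
      upper[i] = hit == 1;
      boundary_hit[i] = true;
    } else {
      if (x > z) upper[i] = true;
      else if (x < z) upper[i] = false;
      else upper[i] = R::unif_rand() < 0.5;
      boundary_hit[i] = false;
    }
  }
  return List::create(_["upper"] = upper, _["boundary_hit"] = boundary_hit);
}
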