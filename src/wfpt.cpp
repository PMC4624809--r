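#include <Rcpp.h>
#include "wfpt.h"
using namespace Rcpp;

// R-facing wrappers around the Wiener first-passage density (see wfpt.h).

// [[Rcpp::export(name = ".wfpt_density_cpp")]]
NumericVector wfpt_density_cpp(NumericVector t, double v, double a,
                               double z_rel, double sv, double precision,
                               bool upper) {
  if (a <= 0.0) stop("boundary separation 'a' must be positive");
  if (z_rel <= 0.0 || z_rel >= 1.0) stop("'z_rel' must be in (0, 1)");
  int n = t.size();
  NumericVector out(n);
  double veff = upper ? -v : v;
  double weff = upper ? 1.0 - z_rel : z_rel;
  for (int i = 0; i < n; ++i)
    out[i] = wfpt::lower_density(t[i], veff, a, weff, sv, precision);
  return out;
}

// Forced-branch kernel evaluation, used to verify that the two series
// representations agree on their overlap region.
// [[Rcpp::export(name = ".wfpt_kernel_branch_cpp")]]
double wfpt_kernel_branch_cpp(double tt, double w, int n_terms,
                              bool small_time) {
  if (small_time) return wfpt::kernel_small(tt, w, n_terms);
  return wfpt::kernel_large(tt, w, n_terms);
}

// Summed log-likelihood of a set of trials sharing one parameter vector.
// [[Rcpp::export(name = ".ddm_loglik_cpp")]]
double ddm_loglik_cpp(NumericVector rt, LogicalVector upper, double v,
                      double a, double z_rel, double t0, double sv, double st,
                      double precision, int n_quad) {
  if (a <= 0.0) stop("boundary separation 'a' must be positive");
  int n = rt.size();
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    double d = wfpt::trial_density(rt[i], upper[i] ? 1 : 0, v, a, z_rel, t0,
                                   sv, st, precision, n_quad);
    if (d <= 0.0) return R_NegInf;
    ll += std::log(d);
  }
  return ll;
}
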