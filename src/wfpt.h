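#ifndef ACCUMAINT_WFPT_H
#define ACCUMAINT_WFPT_H

#include <cmath>
#include <algorithm>

// Shared first-passage-time density core for the two-boundary Wiener
// diffusion (unit diffusion scale). All densities are for absorption at the
// LOWER boundary; map the upper boundary through (v, w) -> (-v, 1 - w).

namespace wfpt {

// Drift-free kernel, small-time expansion with K terms, normalized time tt.
inline double kernel_small(double tt, double w, int K) {
  int lo = -(int)std::floor((K - 1) / 2.0);
  int hi = (int)std::ceil((K - 1) / 2.0);
  double p = 0.0;
  for (int k = lo; k <= hi; ++k) {
    double u = w + 2.0 * k;
    p += u * std::exp(-u * u / (2.0 * tt));
  }
  return p / std::sqrt(2.0 * M_PI * tt * tt * tt);
}

// Drift-free kernel, large-time (Fourier) expansion with K terms.
inline double kernel_large(double tt, double w, int K) {
  double p = 0.0;
  for (int k = 1; k <= K; ++k)
    p += k * std::exp(-k * k * M_PI * M_PI * tt / 2.0) * std::sin(k * M_PI * w);
  return p * M_PI;
}

// Automatic representation switch: truncation lengths chosen so the
// absolute error of the normalized kernel is below `err`; the cheaper
// representation wins.
inline double kernel(double tt, double w, double err) {
  double ks, kl;
  if (M_PI * tt * err < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * tt * err) / (M_PI * M_PI * tt));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(tt)));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(tt));
  }
  if (2.0 * std::sqrt(2.0 * M_PI * tt) * err < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * tt * std::log(2.0 * std::sqrt(2.0 * M_PI * tt) * err));
    ks = std::max(ks, std::sqrt(tt) + 1.0);
  } else {
    ks = 2.0;
  }
  if (ks < kl) return kernel_small(tt, w, (int)std::ceil(ks));
  return kernel_large(tt, w, (int)std::ceil(kl));
}

// Lower-boundary density at decision time t. Trial-to-trial drift
// variability (normal, sd sv) is integrated out in closed form.
inline double lower_density(double t, double v, double a, double w,
                            double sv, double err) {
  if (t <= 0.0) return 0.0;
  double tt = t / (a * a);
  double p = kernel(tt, w, err);
  double mult;
  if (sv > 0.0) {
    double s2t = 1.0 + sv * sv * t;
    mult = std::exp((a * a * w * w * sv * sv - 2.0 * v * a * w - v * v * t) /
                    (2.0 * s2t)) / std::sqrt(s2t);
  } else {
    mult = std::exp(-v * a * w - v * v * t / 2.0);
  }
  return p * mult / (a * a);
}

// Observed-RT density for one trial: non-decision-time variability
// (uniform with range st) integrated by an n_quad-point midpoint rule.
inline double trial_density(double rt, int upper_hit, double v, double a,
                            double w, double t0, double sv, double st,
                            double err, int n_quad) {
  double veff = upper_hit ? -v : v;
  double weff = upper_hit ? 1.0 - w : w;
  if (st <= 1e-6) return lower_density(rt - t0, veff, a, weff, sv, err);
  double d = 0.0;
  for (int q = 0; q < n_quad; ++q) {
    double t0q = t0 - st / 2.0 + st * (q + 0.5) / n_quad;
    d += lower_density(rt - t0q, veff, a, weff, sv, err);
  }
  return d / n_quad;
}

} // namespace wfpt

#endif
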