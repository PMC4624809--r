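---
title: "Models and methods: accumulation, maintenance, and reverse inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: accumulation, maintenance, and reverse inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`accumaint` implements the computational chain used to ask whether the brain
regions that accumulate perceptual evidence also maintain the resulting
choice until a response can be given. The package covers five connected
pieces: (1) forward BOLD predictions that distinguish an
accumulate-and-maintain neuron from an accumulate-only neuron; (2) synthetic
two-alternative forced-choice (2AFC) behavior in an immediate (reaction-time,
RT) and a delayed-response (DR) mode; (3) hierarchical Bayesian models of
accuracy and response time; (4) a hierarchical drift-diffusion model (DDM)
with model comparison; and (5) a coordinate-based reverse-inference
meta-analysis that ranks cognitive terms by their specificity for activated
brain locations. This vignette documents the models, the numerical choices,
and what the synthetic-data checks do and do not establish.

## 1. Forward BOLD predictions

A decision neuron is modeled as a linear firing ramp from baseline `BL` to
threshold `T` over a difficulty-dependent time-to-threshold (hard decisions
ramp longer because evidence accrues more slowly). After threshold, two
mechanisms are distinguished:

* **accumulate-and-maintain** — in the DR condition, firing stays at `T`
  until the response cue; in the RT condition the response occurs at the
  threshold crossing, so firing returns to baseline immediately;
* **accumulate-only** — firing returns to baseline at the threshold crossing
  in both conditions.

The predicted BOLD response is the discrete convolution of the
baseline-subtracted profile with the canonical double-gamma hemodynamic
response function. We use the community-standard HRF constants (peak delay
6 s, undershoot delay 16 s, unit dispersions, peak:undershoot ratio 6, 32 s
kernel); the canonical double gamma is a family, not a single curve, so these
defaults are our choice and are exposed in `hrf_params()`. The amplitude summary is the time-integral of the predicted
curve, because a GLM-style effect scales with integrated activity; a peak
summary is available as an option.

The testable signature is a response-mode by difficulty crossover: an
accumulate-and-maintain region predicts hard > easy integrated BOLD under RT
but easy > hard under DR (easy decisions spend longer at threshold before
the cue), while an accumulate-only region predicts hard > easy in both
modes. `crossover_summary()` reports both contrasts and the flag. The
dichotomy is a structural property of the ramp-plus-hold geometry: a
property test sweeps 100 random valid parameter sets (any `BL < T`, easy
time-to-threshold < hard, cue after both) and the flag follows the mechanism
every time. The prediction is qualitative by design: no particular ramp heights or
times are privileged, only the sign pattern of the two contrasts.

Post-threshold decay is instantaneous by default (`decay_tau = 0`), with an
exponential option. The prediction depends on time-at-threshold, not decay
shape, so the default is the simplest member of the family.

## 2. Synthetic behavior

`experiment_design()` defaults encode the study conditions: 18 participants,
three 112-trial runs (RT, DR, RT), four phase-coherence levels per stimulus
class (easiest first), a 1 s stimulus window, and a 500 ms cued delay plus
500 ms response window in the DR condition.

**Diffusion generator.** `simulate_ddm_dataset()` integrates the
two-boundary Wiener process by Euler–Maruyama with a 0.5 ms step (the
discretization bias at this step is far below the Monte-Carlo error of any
check we run; the step is configurable). The diffusion scale is fixed at 1
and the start point at `a/2` — the standard convention, with no response
bias, matching a design in which face and house are symmetric alternatives.
RT trials whose first passage lands beyond the stimulus window are recorded
as `missed`; at the default study parameters this yields a missed rate of a
few percent on easy trials and substantially more on the hardest level, and
the fitters exclude missed trials, as models of given responses should.
Inter-trial variabilities default to `sv = st = 0` in the generator; the
estimation targets state only level drifts, a boundary and a non-decision
time, and a parsimonious generator keeps recovery interpretable.

**Delayed responses.** Delayed choices need a mechanism, and the simplest
one consistent with a diffusion that keeps running until the cue is chosen:
the generator freezes the evidence state at the response cue: a boundary hit
before the cue decides; otherwise the sign of the accumulated evidence
(ties: coin flip). The recorded DR response time is a motor latency,
N(0.25 s, 0.04 s) truncated to the response window, independent of
difficulty — measured from cue onset, with the cue time carried alongside so
the stimulus-onset convention is recoverable. Counting unanswered trials as
incorrect, DR accuracy is at least RT accuracy under matched parameters,
because the delayed mode answers every trial while the RT window censors the
slowest (disproportionately hard) ones.

**Hierarchical behavior generator.** `simulate_hier_behavior()` draws
exactly the structure the behavior fitters assume: per level, subject
accuracy means from a beta distribution and subject mean RTs from a gamma;
binomial correctness and gamma trial RTs. Defaults are the study-condition
values: group accuracies 0.92/0.84/0.72/0.64, group mean RTs
0.60/0.64/0.72/0.76 s. The 0.10 s spread is the
between-subject sd of subject mean RTs — the quantity the hierarchical
model's group level describes; the trial-level gamma sd defaults to 0.15 s,
a realistic within-subject RT spread, and the accuracy between-subject sd to
0.04, which keeps every level inside the beta family's admissible
mean–variance region. No censoring is applied here: the fitted models
describe given responses, and the generator mirrors the model, not the task
screen.

## 3. Hierarchical behavior models

Response times follow a gamma likelihood whose shape and rate derive from a
mean and variance, `shape = mu^2/sigma^2`, `rate = mu/sigma^2`
(`gamma_shape_rate()`). Per coherence level there is a group gamma over
subject mean RTs and a group gamma over subject RT variances; every gamma is
parameterized by a mean and sd drawn from uniform(0.01, 30) hyperpriors. We
apply those uniforms at every positive hyperparameter level: a single
convention keeps the model transparent.

Accuracy follows a hierarchical beta-binomial: per level, a group mean
`omega` with a flat beta(1, 1) prior and a concentration `kappa` with a
gamma prior whose mean and sd again come from uniform(0.01, 30); subject
accuracy means are beta(`omega kappa`, `(1-omega) kappa`) and correct counts
binomial. We parameterize the group spread through the concentration rather
than placing the prior on the variance directly: a variance-space prior must
be truncated by the state-dependent bound `omega(1-omega)`, which degenerates
as accuracy approaches ceiling (the admissible interval collapses and
samplers stall on the unbounded gamma density), whereas the concentration
form is the standard, numerically stable equivalent — the implied group
variance `omega(1-omega)/(kappa+1)` is reported as `acc_var`. Because the
subject accuracies are conjugate given `(omega, kappa)`, they are
integrated out analytically during sampling (the count likelihood becomes
beta-binomial) and recovered afterwards from their conjugate beta
conditionals; this leaves the joint posterior unchanged while removing the
`omega`/`kappa`/subject funnel that otherwise slows Gibbs samplers. The
group mean is kept a hair inside (0, 1) so ceiling datasets cannot drive
it to an exact endpoint with infinite density.

Both models are fit by Gibbs sampling through JAGS (`rjags`); writing a bespoke sampler for standard conjugate-ish
hierarchies would add risk without adding science. The RT likelihood is
evaluated through per-cell sufficient statistics (`n`, `sum(rt)`,
`sum(log rt)`) with the Poisson zeros trick — an algebraic identity for the
gamma likelihood, so the posterior is unchanged while the graph shrinks from
one node per trial to one per subject-by-level cell.

Reporting machinery: differences between conditions or difficulty groups are
formed on posterior samples (`prob_greater()` — the proportion of paired
difference samples above zero), multiple parameters are combined by the
**grouped chain** (`group_chain()` — the sample-by-sample mean of the
constituent chains with equal weights, not trial-count weighting), uncertainty is a 95% highest-density interval
(`hdi()` — narrowest contiguous window over sorted samples; ties broken by
the first narrowest window), and convergence is the classic Gelman–Rubin
potential scale reduction (`gelman_rubin()`), which requires at least two
chains and refuses single-chain fits.

Default MCMC budget: 3 chains, 2000 burn-in (including adaptation), 5000
kept samples, no thinning.

## 4. Hierarchical drift diffusion model

The DDM likelihood is the Wiener first-passage-time density. The drift-free
kernel is evaluated in normalized time with dual series — a small-time
expansion and a large-time Fourier expansion — with truncation lengths
chosen so the absolute error is below a target (1e-7 by default) and the
cheaper representation selected automatically. The two representations agree
to 1e-6 on their overlap, and the integrated density matches the closed-form
hit probability `(1 - exp(-2 v z)) / (1 - exp(-2 v a))`; both are tested.
Trial-to-trial drift variability (normal, sd `sv`) is integrated in closed
form; non-decision-time variability (uniform range `st`) by a midpoint rule
(3 nodes by default). With `sv = st = 0` the likelihood reduces exactly to
the plain density.

Four variants differ in what varies across coherence levels: `m1` drift and
boundary (the full model), `m2` nothing, `m3` drift only, `m4` boundary
only. All estimate subject non-decision times and group-level `sv` and
`st`; the start point stays at `a/2` and is not fit. Hierarchies: drifts are
normal per level; boundaries and non-decision times log-normal (positive
support, right-skew across subjects); `sv` and `st` have bounded uniform
priors and are sampled on their natural scale with reflective random walks —
their posteriors sit near zero on recovery data, where a log-scale walk
mixes poorly against the boundary.

The sampler is Metropolis-within-Gibbs in compiled code: adaptive
random-walk proposals per scalar parameter (step sizes tuned toward 0.44
acceptance during burn-in and frozen afterwards, so the kept samples come
from a fixed kernel), conjugate Gibbs draws for the group-level normal
means, and two structured moves that target the posterior's known ridges:

* a **non-decision-time ridge move** — the fastest observed responses pin
  `t0 - st/2`, making `st` and the non-decision times strongly
  anticorrelated; the move translates `st` and every subject's `t0` along
  the ridge (keeping `t0 - st/2` fixed) with the appropriate log-normal
  Jacobian. Between cheap random-walk translations, every fifth iteration
  runs a shrinking-interval slice draw along the same direction, which
  traverses the whole admissible `st` range at the cost of a few full-data
  evaluations;
* a **funnel scale move per boundary level** — when subjects are
  homogeneous the group sd piles near its lower bound and pinches the
  subject deviations; the move rescales the sd and the deviations
  together (the prior ratio cancels against the Jacobian), and the group
  sds themselves are drawn by shrinking-interval slice sampling within
  their uniform bounds;
* **per-subject adaptive-covariance jumps** — drift, boundary and
  non-decision time are correlated within a subject, so the sampler learns
  each subject's parameter covariance during burn-in (online estimate,
  Cholesky refreshed periodically, frozen at the end of burn-in) and
  proposes joint moves along it, scaled toward 0.25 acceptance.

Deviance samples (-2 log-likelihood) are stored each kept iteration; DIC
uses the plug-in effective parameter count, `pD = Dbar - D(posterior
means)`, and `DIC = Dbar + pD`. Absolute DIC values depend on the particular dataset; what is
testable on synthetic data — and tested — is model recovery: on data generated with
level-dependent drift and boundary, `m1` attains the lowest DIC in at least
9 of 10 seeded replicates. Posterior predictive checks resimulate datasets
from sampled parameters, coding error responses with negative response
times for overlay plots, and replicate the fitted data's accuracy and
correct-RT quantiles within ±0.05 on recovery data.

The DDM applies to the RT condition only — it models a response given at
boundary crossing — and `fit_hddm()` rejects DR trials.

## 5. Reverse-inference meta-analysis

The meta-analysis machinery reproduces the extended Neurosynth-style chain
on synthetic corpora.

* **Term database** — article texts (title + abstract + keywords) are
  lowercased, stop-word filtered (list shipped as a plain-text fixture) and
  stemmed with a full Porter (1980) stemmer implemented in the package (no
  stemming package is available in the target environment; the
  implementation is validated against the algorithm's published worked
  examples). A term — one or two words — is assigned to an article iff its
  stemmed form occurs, two-word terms as consecutive stemmed tokens. Terms
  in fewer than 15 articles and an exclusion list ("face*", "house",
  "picture", "actor") are removed.
* **Location database** — article id to MNI foci; `merge_foci()` unions two
  databases by id with exact deduplication. Activation is binarized on a
  voxel grid: a voxel is active for an article iff it lies within 10 mm of
  any focus (the coordinate-based meta-analysis convention; the radius and
  grid are configurable, and tests use coarse grids for speed).
* **Posterior maps** — per voxel, `p(Term | Actv.)` by Bayes' rule from the
  activation fractions among with-term and without-term articles, with a
  default prior `p(Term) = 0.5` (the Neurosynth specificity convention; the
  empirical frequency is an option). Association z-maps come from the
  Pearson chi-square (no continuity correction) on the 2x2 term-by-active
  counts, converted through the two-sided p-value to an absolute z, signed
  by the direction of association. A chi-square can be formed on counts or on
  estimated probabilities; we test counts, the construction that has a
  sampling distribution.
* **Peaks and scores** — local maxima of a contrast map above z = 2.3
  (26-connectivity) are selected greedily in descending order with a 30 mm
  minimum separation (configurable; 3 cm is a common cluster-tool setting,
  though some pipelines use 3 mm). Around
  each peak, a 5 mm sphere averages the term's posterior z weighted by the
  contrast z normalized to unit sum; non-positive contrast weights are
  clamped to zero first so the weights form a convex combination, and
  missing posterior-z voxels are dropped with renormalization. The evidence
  score is the peak contrast z times this ROI average; per contrast, each
  term keeps its best peak, the top 8 terms are reported (top 3 for a
  single-cluster contrast).

The synthetic corpus generator plants term–region associations (activation
probability 0.8 given the term versus a 0.1 base rate by default) over
uniform background foci, and the planted term wins the evidence ranking in
at least 9 of 10 seeds — an end-to-end check of the whole chain against its
construction. The generator does not emulate real corpora's correlated term
usage, spatial smoothness of reporting conventions, or heterogeneous
article quality, so passing these checks validates the arithmetic of the
pipeline, not the epistemics of reverse inference on real literature.

## 6. Problem sizes, budgets and degenerate inputs

The simulation checks run the study design (18 subjects; 84 behavioral
trials per subject and level; 100 DDM trials per subject and level per run
over two RT runs) at the default MCMC budget; the DDM convergence summary
uses 10000 kept samples per chain, since the Gelman–Rubin statistic itself
is noisy at small effective sample sizes and a tight convergence claim
needs chains long enough to support it. Unit tests use smaller replicas of
the same generators so the suite stays fast. Degenerate inputs
are defined: empty trial sets have log-likelihood 0; a response time at or
below the non-decision time has zero density and makes a trial's
contribution -Inf; voxels where no article is active have undefined
posterior (missing); a design with zero subjects yields an empty, correctly
typed trial table. Determinism is part of every interface contract: all
randomness flows through explicit seeds, and equal seeds give bit-identical
trial tables, corpora, chains and reports.

Known limitations: the behavioral and DDM posteriors are validated by
parameter recovery on synthetic data, not against estimates from any real
participant sample; censoring at the 1 s RT window
biases DDM recovery slightly at the hardest level, which is visible as a
modest boundary underestimate when fitting heavily censored data; and the
reverse-inference scores inherit every caveat of coordinate-based
meta-analysis.
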