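# shared fixtures: small designs, quick MCMC budgets, toy grids

tiny_design <- function(n_subjects = 4, trials_per_run = 24,
                        runs = c("RT", "DR"), ...) {
  experiment_design(n_subjects = n_subjects, trials_per_run = trials_per_run,
                    runs = runs, ...)
}

quick_cfg <- function(chains = 2, samples = 400, burnin = 300) {
  mcmc_config(chains = chains, samples = samples, burnin = burnin)
}

toy_grid <- function(n = 10, spacing = 4) {
  half <- (n - 1) * spacing / 2
  voxel_grid(c(n, n, n), spacing, origin = c(-half, -half, -half))
}

# brute-force Bayes oracle for the reverse-inference posterior: recompute
# p(Term | Actv.) from raw article counts at one voxel
bayes_oracle <- function(active_with, n_with, active_without, n_without,
                         prior) {
  pa_t <- active_with / n_with
  pa_nt <- active_without / n_without
  den <- pa_t * prior + pa_nt * (1 - prior)
  if (den == 0) return(NA_real_)
  pa_t * prior / den
}

# exhaustive-search HDI oracle: scan every contiguous window of the sorted
# samples that holds ceiling(mass * n) points and keep the narrowest
hdi_oracle <- function(samples, mass = 0.95) {
  s <- sort(samples)
  n <- length(s)
  k <- ceiling(mass * n)
  best <- c(-Inf, Inf)
  for (i in seq_len(n - k + 1)) {
    lo <- s[i]
    hi <- s[i + k - 1]
    if (hi - lo < best[2] - best[1]) best <- c(lo, hi)
  }
  best
}

# DDM dataset with known per-subject parameters drawn around group values
recovery_ddm_trials <- function(n_subjects, trials_per_run, seed,
                                v_group = c(2.2, 1.8, 1.0, 0.6),
                                v_sd = 0.3, a = 1.5, t0 = 0.3,
                                stimulus_window_s = 1, runs = c("RT", "RT")) {
  design <- experiment_design(n_subjects = n_subjects,
                              trials_per_run = trials_per_run, runs = runs,
                              stimulus_window_s = stimulus_window_s)
  params <- lapply(seq_len(n_subjects), function(j) {
    set.seed(seed * 1000 + j)
    ddm_params(v = rnorm(length(v_group), v_group, v_sd), a = a, t0 = t0)
  })
  simulate_ddm_dataset(design, params, seed = seed)
}
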