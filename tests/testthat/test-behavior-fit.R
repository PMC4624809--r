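# Hierarchical behavior model fits. Budgets here are reduced relative to the
# package defaults; recovery tolerances account for the finite number of
# subjects (generating between-subject sds are chosen so the group-mean
# standard error stays well inside the asserted bands).

test_that("the RT model recovers a known group mean", {
  gp <- hier_behavior_params(acc_mean = c(0.8, 0.8), rt_mean = c(0.7, 0.7),
                             acc_subject_sd = 0.04, rt_subject_sd = 0.05,
                             rt_trial_sd = 0.15)
  d <- experiment_design(n_subjects = 18)
  tt <- simulate_hier_behavior(d, gp, seed = 41, trials_per_level = 100)
  fit <- fit_rt_model(tt, "RT", mcmc_config(3, 1500, 1000), seed = 41)
  m1 <- mean(chain_samples(fit, "rt_mean[1]", pooled = TRUE))
  expect_gt(m1, 0.67)
  expect_lt(m1, 0.73)
})

test_that("a null contrast gives no systematic evidence either way", {
  # identically generated levels: the posterior probability of a positive
  # difference behaves like a posterior p-value, roughly uniform across
  # replicates, so its average should sit near one half
  gp <- hier_behavior_params(acc_mean = c(0.8, 0.8), rt_mean = c(0.7, 0.7),
                             rt_subject_sd = 0.05, rt_trial_sd = 0.15)
  d <- experiment_design(n_subjects = 10)
  ps <- vapply(1:8, function(rep) {
    tt <- simulate_hier_behavior(d, gp, seed = 240 + rep,
                                 trials_per_level = 60)
    fit <- fit_rt_model(tt, "RT", mcmc_config(2, 400, 400), seed = 240 + rep)
    prob_greater(chain_samples(fit, "rt_mean[1]", pooled = TRUE),
                 chain_samples(fit, "rt_mean[2]", pooled = TRUE))
  }, numeric(1))
  expect_gt(mean(ps), 0.15)
  expect_lt(mean(ps), 0.85)
})

test_that("a ceiling-accuracy dataset pushes the group mean above 0.95", {
  counts <- expand.grid(subject = 1:18, coherence_level = 1:2)
  counts$N <- 50
  counts$z <- 50
  fit <- fit_accuracy_model(counts = counts,
                            mcmc_cfg = mcmc_config(2, 800, 500), seed = 8)
  expect_gt(mean(chain_samples(fit, "acc_mean[1]", pooled = TRUE)), 0.95)
})

test_that("well-separated accuracy levels are ordered correctly across replicates", {
  gp <- hier_behavior_params(acc_mean = c(0.9, 0.6), rt_mean = c(0.6, 0.7),
                             acc_subject_sd = 0.04)
  d <- experiment_design(n_subjects = 10)
  ok <- 0
  for (rep in 1:20) {
    tt <- simulate_hier_behavior(d, gp, seed = 500 + rep,
                                 trials_per_level = 40)
    fit <- fit_accuracy_model(tt, "RT", mcmc_config(2, 300, 300),
                              seed = 500 + rep)
    m <- c(mean(chain_samples(fit, "acc_mean[1]", pooled = TRUE)),
           mean(chain_samples(fit, "acc_mean[2]", pooled = TRUE)))
    if (m[1] > m[2]) ok <- ok + 1
  }
  expect_gte(ok, 19)
})

test_that("fit inputs are validated", {
  counts <- data.frame(subject = 1:3, coherence_level = 1, z = c(5, 60, 5),
                       N = 50)
  expect_error(fit_accuracy_model(counts = counts), "exceeds")
  d <- experiment_design(n_subjects = 3)
  tt <- simulate_hier_behavior(d, hier_behavior_params(), seed = 1,
                               trials_per_level = 10)
  tt <- tt[!(tt$subject == 2 & tt$coherence_level == 3), ]
  expect_error(fit_rt_model(tt, "RT", quick_cfg()), "subject 2, level 3")
  expect_error(fit_rt_model(tt[tt$subject == 1, ], "RT"), "2 subjects")
  expect_warning(mcmc_config(burnin = 0), "burn-in")
})

test_that("single-chain fits are allowed but convergence diagnostics refuse", {
  d <- experiment_design(n_subjects = 4)
  tt <- simulate_hier_behavior(d, hier_behavior_params(), seed = 2,
                               trials_per_level = 20)
  fit <- fit_accuracy_model(tt, "RT", mcmc_config(1, 200, 200), seed = 2)
  expect_equal(nrow(fit$samples[["acc_mean[1]"]]), 1)
  expect_error(gelman_rubin(fit, "acc_mean[1]"), "2 chains")
})

test_that("fits are reproducible given the seed", {
  d <- experiment_design(n_subjects = 4)
  tt <- simulate_hier_behavior(d, hier_behavior_params(), seed = 3,
                               trials_per_level = 20)
  f1 <- fit_rt_model(tt, "RT", mcmc_config(2, 200, 200), seed = 11)
  f2 <- fit_rt_model(tt, "RT", mcmc_config(2, 200, 200), seed = 11)
  expect_identical(f1$samples, f2$samples)
})

test_that("group-level 95% HDIs cover the generating means", {
  # moderate-scale coverage sweep: accuracy and RT group means per level
  d <- experiment_design(n_subjects = 18)
  gp <- hier_behavior_params()
  covered <- 0
  total <- 0
  for (rep in 1:5) {
    tt <- simulate_hier_behavior(d, gp, seed = 900 + rep,
                                 trials_per_level = 75)
    fa <- fit_accuracy_model(tt, "RT", mcmc_config(2, 1000, 700),
                             seed = 900 + rep)
    fr <- fit_rt_model(tt, "RT", mcmc_config(2, 1000, 700), seed = 900 + rep)
    for (c in 1:4) {
      iv <- hdi(chain_samples(fa, sprintf("acc_mean[%d]", c), pooled = TRUE))
      covered <- covered + (gp$acc_mean[c] >= iv[1] && gp$acc_mean[c] <= iv[2])
      iv <- hdi(chain_samples(fr, sprintf("rt_mean[%d]", c), pooled = TRUE))
      covered <- covered + (gp$rt_mean[c] >= iv[1] && gp$rt_mean[c] <= iv[2])
      total <- total + 2
    }
  }
  expect_gte(covered / total, 0.9)
})
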