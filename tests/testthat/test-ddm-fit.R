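# Hierarchical DDM fits at reduced scale. A 4 s stimulus window keeps the
# datasets effectively uncensored so generating values are recoverable;
# the study window (1 s) is exercised by the censoring tests elsewhere.

test_that("the hierarchical DDM recovers drift ordering and boundary", {
  tt <- recovery_ddm_trials(n_subjects = 10, trials_per_run = 200, seed = 61,
                            stimulus_window_s = 4)
  fit <- fit_hddm(tt, ddm_model_spec("m1"), mcmc_config(2, 800, 800),
                  seed = 61)
  v <- vapply(sprintf("v_mean[%d]", 1:4), function(p) {
    mean(chain_samples(fit, p, pooled = TRUE))
  }, numeric(1))
  expect_equal(order(-v), 1:4)  # generating drifts decrease with difficulty
  a_mean <- mean(exp(grouped_parameter_chain(
    fit, sprintf("log_a_mean[%d]", 1:4))))
  expect_gt(a_mean, 1.35)  # generating boundary 1.5 +/- 10%
  expect_lt(a_mean, 1.65)
  t_mean <- mean(exp(chain_samples(fit, "log_t_mean", pooled = TRUE)))
  expect_lt(abs(t_mean - 0.3), 0.05)
})

test_that("fits are deterministic given seed and reject DR trials", {
  tt <- recovery_ddm_trials(n_subjects = 3, trials_per_run = 40, seed = 62,
                            stimulus_window_s = 4)
  cfg <- mcmc_config(2, 100, 100)
  f1 <- fit_hddm(tt, ddm_model_spec("m3"), cfg, seed = 5)
  f2 <- fit_hddm(tt, ddm_model_spec("m3"), cfg, seed = 5)
  expect_identical(f1$samples, f2$samples)
  dr <- tt
  dr$condition <- "DR"
  expect_error(fit_hddm(dr, ddm_model_spec("m1"), cfg), "delayed-response")
})

test_that("model variants expose the stated difficulty structure", {
  expect_true(ddm_model_spec("m1")$vary_v && ddm_model_spec("m1")$vary_a)
  expect_false(ddm_model_spec("m2")$vary_v || ddm_model_spec("m2")$vary_a)
  expect_true(ddm_model_spec("m3")$vary_v && !ddm_model_spec("m3")$vary_a)
  expect_true(!ddm_model_spec("m4")$vary_v && ddm_model_spec("m4")$vary_a)
  tt <- recovery_ddm_trials(n_subjects = 3, trials_per_run = 40, seed = 63,
                            stimulus_window_s = 4)
  f2 <- fit_hddm(tt, ddm_model_spec("m2"), mcmc_config(2, 100, 100), seed = 1)
  expect_true("v_mean" %in% names(f2$samples))      # no per-level index
  expect_false("v_mean[1]" %in% names(f2$samples))
})

test_that("DIC follows its definition and flags undersampled posteriors", {
  tt <- recovery_ddm_trials(n_subjects = 4, trials_per_run = 60, seed = 64,
                            stimulus_window_s = 4)
  fit <- fit_hddm(tt, ddm_model_spec("m1"), mcmc_config(2, 400, 400),
                  seed = 2)
  d1 <- dic(fit)
  expect_equal(d1$dic, d1$mean_deviance + d1$pd)
  expect_gt(d1$pd, 0)
  expect_equal(dic(fit)$dic, d1$dic)  # same posterior, identical DIC
  short <- fit
  short$deviance <- fit$deviance[, 1:30, drop = FALSE]
  expect_error(dic(short), "100 deviance samples")
})

test_that("DIC prefers the generating difficulty structure over a flat model", {
  wins <- 0
  for (rep in 1:10) {
    tt <- recovery_ddm_trials(n_subjects = 6, trials_per_run = 100,
                              seed = 700 + rep, stimulus_window_s = 4,
                              v_group = c(2.4, 2.0, 1.0, 0.5), v_sd = 0.2)
    cfg <- mcmc_config(1, 500, 400)
    f1 <- fit_hddm(tt, ddm_model_spec("m1"), cfg, seed = 700 + rep)
    f2 <- fit_hddm(tt, ddm_model_spec("m2"), cfg, seed = 700 + rep)
    if (dic(f1)$dic < dic(f2)$dic) wins <- wins + 1
  }
  expect_gte(wins, 9)
})

test_that("posterior predictive datasets replicate accuracy and RT quantiles", {
  tt <- recovery_ddm_trials(n_subjects = 8, trials_per_run = 150, seed = 65,
                            stimulus_window_s = 4)
  fit <- fit_hddm(tt, ddm_model_spec("m1"), mcmc_config(2, 600, 600),
                  seed = 65)
  pp <- posterior_predictive(fit, n_draws = 30, seed = 66)
  expect_true(all(pp$rt[pp$correct] > 0))
  expect_true(all(pp$rt[!pp$correct] < 0))  # errors coded negative
  obs <- tt[tt$choice != "missed", ]
  for (lev in c(1, 4)) {
    acc_obs <- mean(obs$correct[obs$coherence_level == lev])
    acc_pp <- mean(pp$correct[pp$coherence_level == lev])
    expect_lt(abs(acc_obs - acc_pp), 0.05)
    q_obs <- quantile(obs$rt[obs$coherence_level == lev & obs$correct],
                      c(0.1, 0.5, 0.9))
    q_pp <- quantile(pp$rt[pp$coherence_level == lev & pp$correct],
                     c(0.1, 0.5, 0.9))
    # the .9 quantile of the long right tail carries most of the posterior
    # predictive spread, so it gets a wider band than the bulk quantiles
    expect_true(all(abs(q_obs - q_pp) < c(0.05, 0.05, 0.1)),
                label = sprintf("level %d quantiles", lev))
  }
  expect_equal(nrow(posterior_predictive(fit, n_draws = 0)), 0)
})
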