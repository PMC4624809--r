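test_that("simulated choice fractions match the closed-form hit probability", {
  combos <- expand.grid(v = c(-1, 0, 0.6, 1, 2.2), a = c(1, 1.5, 2))
  n <- 4000
  set.seed(42)
  for (i in seq_len(nrow(combos))) {
    v <- combos$v[i]
    a <- combos$a[i]
    sim <- simulate_ddm_trials(n, ddm_params(v = v, a = a, t0 = 0))
    p_hat <- mean(sim$upper, na.rm = TRUE)
    p <- ddm_hit_probability(v, a)
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(p_hat - p), 3 * se + 1e-6,
              label = sprintf("v=%g a=%g: |%g - %g|", v, a, p_hat, p))
  }
})

test_that("drift-free diffusion splits choices evenly", {
  set.seed(7)
  sim <- simulate_ddm_trials(1e4, ddm_params(v = 0, a = 2, t0 = 0))
  expect_lt(abs(mean(sim$upper) - 0.5), 3 * sqrt(0.25 / 1e4))
})

test_that("easier discriminations are faster and more accurate", {
  set.seed(11)
  easy <- simulate_ddm_trials(1e4, ddm_params(v = 2.2, a = 1.5, t0 = 0.3))
  hard <- simulate_ddm_trials(1e4, ddm_params(v = 0.6, a = 1.5, t0 = 0.3))
  expect_gt(mean(easy$upper), mean(hard$upper))
  expect_lt(mean(easy$rt[easy$upper]), mean(hard$rt[hard$upper]))
})

test_that("RT-condition trials beyond the stimulus window are censored as missed", {
  d <- tiny_design(n_subjects = 3, trials_per_run = 40, runs = "RT")
  tt <- simulate_ddm_dataset(d, ddm_params(v = 0.3, a = 2.5, t0 = 0.3),
                             seed = 2)
  expect_true(all(tt$rt[tt$choice != "missed"] <= d$stimulus_window_s))
  expect_true(all(is.na(tt$rt[tt$choice == "missed"])))
  expect_gt(sum(tt$choice == "missed"), 0) # slow diffusion must miss some
  expect_true(all(tt$correct == (tt$choice == tt$stimulus)))
})

test_that("the trial table is reproducible from the seed", {
  d <- tiny_design(n_subjects = 2, trials_per_run = 16, runs = "RT")
  p <- ddm_params(v = c(2, 1.5, 1, 0.5), a = 1.5)
  expect_identical(simulate_ddm_dataset(d, p, seed = 9),
                   simulate_ddm_dataset(d, p, seed = 9))
  dr <- tiny_design(n_subjects = 2, trials_per_run = 16, runs = "DR")
  expect_identical(simulate_dr_dataset(dr, p, seed = 9),
                   simulate_dr_dataset(dr, p, seed = 9))
})

test_that("invalid diffusion parameters are rejected", {
  expect_error(ddm_params(v = 1, a = -1), "positive")
  expect_error(ddm_params(v = 1, a = 1, z_rel = 1.2), "z_rel")
  expect_error(ddm_params(v = 1, a = 1, t0 = -0.1), "t0")
  expect_error(experiment_design(stimulus_window_s = 0), "positive")
})

test_that("delayed responses are at least as accurate as immediate ones", {
  p <- ddm_params(v = c(2.2, 1.8, 1.0, 0.6), a = 1.5, t0 = 0.3)
  d <- experiment_design(n_subjects = 8, trials_per_run = 112,
                         runs = c("RT", "DR"))
  rt <- simulate_ddm_dataset(d, p, seed = 21)
  dr <- simulate_dr_dataset(d, p, seed = 22)
  # accuracy over all trials: missed trials (unanswered within the window)
  # are not correct, which is what the delayed response removes
  expect_gte(mean(dr$correct), mean(rt$correct))
})

test_that("DR response times are difficulty-independent motor latencies", {
  p <- ddm_params(v = c(2.2, 1.8, 1.0, 0.6), a = 1.5, t0 = 0.3)
  d <- experiment_design(n_subjects = 10, trials_per_run = 112, runs = "DR")
  dr <- simulate_dr_dataset(d, p, seed = 5)
  ok <- dr$choice != "missed"
  easy <- dr$coherence_level <= 2
  expect_lt(abs(mean(dr$rt[ok & easy]) - 0.25), 0.01)
  expect_lt(abs(mean(dr$rt[ok & !easy]) - 0.25), 0.01)
  expect_true(all(dr$rt[ok] <= d$dr_response_window_s))
  expect_equal(unique(dr$cue_onset_s), 1.5)
})

test_that("DR latencies beyond the response window are marked missed", {
  p <- ddm_params(v = 2, a = 1.5, t0 = 0.3)
  d <- tiny_design(n_subjects = 2, trials_per_run = 30, runs = "DR")
  dr <- simulate_dr_dataset(d, p, seed = 3, motor_mean = 0.65,
                            motor_sd = 0.01)
  expect_true(all(dr$choice == "missed")) # latency ~N(0.65) > 0.5 s window
})

test_that("trial tables round-trip through CSV", {
  d <- tiny_design(n_subjects = 2, trials_per_run = 8, runs = "RT")
  tt <- simulate_ddm_dataset(d, ddm_params(v = 1, a = 1.5), seed = 1)
  path <- tempfile(fileext = ".csv")
  write_trial_table(tt, path)
  back <- read_trial_table(path)
  expect_equal(back, tt[, names(back)])
})
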