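test_that("the firing ramp interpolates linearly from baseline to threshold", {
  fp <- firing_params(baseline = 5, threshold = 50,
                      time_to_threshold = c(easy = 0.5, hard = 0.8),
                      maintenance_until = 1.5)
  prof <- firing_profile(fp, "easy", "RT", dt = 0.01)
  expect_equal(prof$values[1], 5)                      # t = 0: baseline
  expect_equal(prof$values[prof$t == 0.25], 27.5)      # midway up the ramp
  expect_equal(max(prof$values), 50)
})

test_that("maintenance time at threshold is longer for easy decisions", {
  fp <- firing_params(time_to_threshold = c(easy = 0.4, hard = 0.8),
                      maintenance_until = 1.5)
  at_thresh <- function(diff) {
    p <- firing_profile(fp, diff, "DR", dt = 0.001)
    sum(p$values == fp$threshold) * p$dt
  }
  expect_equal(at_thresh("easy"), 1.1, tolerance = 0.01)
  expect_equal(at_thresh("hard"), 0.7, tolerance = 0.01)
})

test_that("a response cue before threshold crossing is rejected", {
  fp <- firing_params(time_to_threshold = c(easy = 0.4, hard = 0.8),
                      maintenance_until = 0.6)
  expect_error(firing_profile(fp, "hard", "DR"), "precedes")
  expect_silent(firing_profile(fp, "easy", "DR"))
  expect_error(firing_params(threshold = 4, baseline = 5), "exceed")
  expect_error(firing_params(time_to_threshold = c(easy = 0.8, hard = 0.4)),
               "longer")
})

test_that("the canonical double-gamma kernel peaks near 5 s at unit height", {
  k <- canonical_hrf(0.1)
  expect_equal(max(k), 1)
  expect_lt(abs((which.max(k) - 1) * 0.1 - 5), 0.2)
  k2 <- canonical_hrf(0.05)
  expect_lt(abs((which.max(k2) - 1) * 0.05 - (which.max(k) - 1) * 0.1), 0.1)
  expect_error(canonical_hrf(0), "positive")
  expect_error(hrf_params(peak_delay = -1), "positive")
})

test_that("BOLD prediction is a linear convolution of the firing deviation", {
  fp <- firing_params()
  k <- canonical_hrf(0.01)
  prof <- firing_profile(fp, "easy", "DR", dt = 0.01)
  flat <- prof
  flat$values <- rep(fp$baseline, length(prof$values))
  expect_equal(max(abs(predict_bold(flat, k)$values)), 0)
  b1 <- predict_bold(prof, k)
  doubled <- prof
  doubled$values <- fp$baseline + 2 * (prof$values - fp$baseline)
  expect_equal(predict_bold(doubled, k)$values, 2 * b1$values,
               tolerance = 1e-10)
  # a unit impulse reproduces the kernel
  imp <- flat
  imp$values[10] <- fp$baseline + 1
  got <- predict_bold(imp, k)$values
  expect_equal(got[10:(9 + length(k))], as.numeric(k), tolerance = 1e-8)
  bad <- prof
  bad$dt <- 0.02
  expect_error(predict_bold(bad, k), "time step")
})

test_that("accumulate-and-maintain predicts the crossover, accumulate-only does not", {
  k <- canonical_hrf(0.01)
  run_mode <- function(mode) {
    fp <- firing_params(mode = mode)
    bold <- lapply(c(easy_rt = "easy.RT", hard_rt = "hard.RT",
                     easy_dr = "easy.DR", hard_dr = "hard.DR"),
                   function(s) {
                     parts <- strsplit(s, ".", fixed = TRUE)[[1]]
                     predict_bold(firing_profile(fp, parts[1], parts[2],
                                                 dt = 0.01,
                                                 duration = 3), k)
                   })
    crossover_summary(bold$easy_rt, bold$hard_rt, bold$easy_dr, bold$hard_dr)
  }
  cs_am <- run_mode("accumulate_maintain")
  expect_true(cs_am$crossover)
  cs_ao <- run_mode("accumulate_only")
  expect_false(cs_ao$crossover)
  expect_gt(cs_ao$rt_hard_minus_easy, 0)
  expect_lt(cs_ao$dr_easy_minus_hard, 0)  # hard > easy in both conditions
})

test_that("identical easy/hard profiles give zero differences and no crossover", {
  fp <- firing_params()
  k <- canonical_hrf(0.01)
  b <- predict_bold(firing_profile(fp, "easy", "RT", duration = 3), k)
  cs <- crossover_summary(b, b, b, b)
  expect_equal(cs$rt_hard_minus_easy, 0)
  expect_equal(cs$dr_easy_minus_hard, 0)
  expect_false(cs$crossover)
})

test_that("the crossover dichotomy holds across random valid parameter sets", {
  set.seed(99)
  k <- canonical_hrf(0.02)
  for (i in 1:100) {
    bl <- runif(1, 1, 10)
    th <- bl + runif(1, 20, 60)
    easy <- runif(1, 0.2, 0.6)
    hard <- easy + runif(1, 0.1, 0.6)
    cue <- hard + runif(1, 0.1, 1)
    mode <- if (i %% 2 == 0) "accumulate_maintain" else "accumulate_only"
    fp <- firing_params(baseline = bl, threshold = th,
                        time_to_threshold = c(easy = easy, hard = hard),
                        maintenance_until = cue, mode = mode)
    bold <- lapply(list(c("easy", "RT"), c("hard", "RT"),
                        c("easy", "DR"), c("hard", "DR")),
                   function(p) predict_bold(
                     firing_profile(fp, p[1], p[2], dt = 0.02,
                                    duration = cue + 1), k))
    cs <- crossover_summary(bold[[1]], bold[[2]], bold[[3]], bold[[4]])
    expect_equal(cs$crossover, mode == "accumulate_maintain",
                 label = sprintf("set %d (%s)", i, mode))
  }
})
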