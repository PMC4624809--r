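#' Drift-diffusion generating parameters for one subject
#'
#' Parameters of the two-boundary Wiener diffusion used to generate 2AFC
#' trials. Evidence for the two response options is subtracted and the
#' difference accumulates between boundaries 0 and `a`; the upper boundary
#' is the correct response. The diffusion scale is fixed at 1 and the start
#' point at `z_rel * a` (default midway, i.e. no response bias).
#'
#' @param v drift rate per coherence level (evidence units/s); length 1 or
#'   one per level. Positive drift favours the correct boundary.
#' @param a boundary separation per level; length 1 or one per level.
#' @param t0 non-decision time, seconds (>= 0).
#' @param sv trial-to-trial drift standard deviation (>= 0).
#' @param st trial-to-trial non-decision-time range, seconds (>= 0).
#' @param z_rel relative start point in (0, 1); fixed at 0.5 by default.
#' @return object of class `ddm_params`.
#' @examples
#' ddm_params(v = c(2.2, 1.8, 1.0, 0.6), a = 1.5, t0 = 0.3)
#' @export
ddm_params <- function(v, a, t0 = 0.3, sv = 0, st = 0, z_rel = 0.5) {
  if (any(a <= 0)) stop("boundary separation 'a' must be positive")
  if (z_rel <= 0 || z_rel >= 1) stop("'z_rel' must be in (0, 1)")
  if (t0 < 0) stop("non-decision time 't0' must be >= 0")
  if (sv < 0 || st < 0) stop("'sv' and 'st' must be >= 0")
  structure(list(v = v, a = a, t0 = t0, sv = sv, st = st, z_rel = z_rel),
            class = "ddm_params")
}

resolve_subject_params <- function(params, n_subjects) {
  if (inherits(params, "ddm_params")) {
    return(replicate(n_subjects, params, simplify = FALSE))
  }
  stopifnot(is.list(params), length(params) == n_subjects)
  lapply(params, function(p) {
    if (!inherits(p, "ddm_params")) stop("each element must be a 'ddm_params'")
    p
  })
}

level_par <- function(x, level) if (length(x) == 1) x else x[level]

#' Simulate reaction-time-condition trials from the drift diffusion model
#'
#' Generates one trial record per trial of every RT run in the design, by
#' Euler--Maruyama integration of the diffusion (default step 0.5 ms).
#' Trials whose first passage occurs after the stimulus window are recorded
#' as `missed` (this censoring yields a missed-trial rate of roughly 4% at
#' the default study parameters).
#'
#' @param design an [experiment_design()].
#' @param params a single [ddm_params()] (shared by all subjects) or a list
#'   with one `ddm_params` per subject.
#' @param seed integer seed; the same seed reproduces the table exactly.
#' @param dt integration step, seconds.
#' @param max_t simulation horizon, seconds.
#' @return trial table data frame with columns
#'   `subject,condition,coherence_level,stimulus,choice,correct,rt`.
#' @examples
#' d <- experiment_design(n_subjects = 2, trials_per_run = 16)
#' head(simulate_ddm_dataset(d, ddm_params(v = 1.5, a = 1.5), seed = 1))
#' @export
simulate_ddm_dataset <- function(design, params, seed, dt = 5e-4, max_t = 10) {
  stopifnot(inherits(design, "experiment_design"))
  if (design$stimulus_window_s <= 0) stop("stimulus window must be positive")
  subj_par <- resolve_subject_params(params, design$n_subjects)
  set.seed(seed)
  out <- list()
  rt_runs <- sum(design$runs == "RT")
  if (rt_runs == 0) stop("design contains no RT run")
  for (j in seq_len(design$n_subjects)) {
    p <- subj_par[[j]]
    for (run in seq_len(rt_runs)) {
      lay <- run_trial_layout(design$trials_per_run)
      rts <- numeric(nrow(lay))
      ups <- logical(nrow(lay))
      for (i in seq_len(nrow(lay))) {
        sim <- .ddm_sim_cpp(1L, level_par(p$v, lay$level[i]),
                            level_par(p$a, lay$level[i]), p$z_rel, p$t0,
                            p$sv, p$st, dt, max_t)
        rts[i] <- sim$rt
        ups[i] <- isTRUE(sim$upper)
      }
      missed <- is.na(rts) | rts > design$stimulus_window_s
      other <- ifelse(lay$stimulus == "face", "house", "face")
      choice <- ifelse(missed, "missed", ifelse(ups, lay$stimulus, other))
      out[[length(out) + 1]] <- data.frame(
        subject = j, condition = "RT", coherence_level = lay$level,
        stimulus = lay$stimulus, choice = choice,
        correct = choice == lay$stimulus,
        rt = ifelse(missed, NA_real_, rts))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate delayed-response-condition trials
#'
#' Evidence accumulates during the stimulus window and the cued delay; at
#' the response cue the evidence state is frozen. If a boundary was reached
#' before the cue that choice is given, otherwise the sign of the
#' accumulated evidence relative to the start point determines the choice.
#' Because accumulation may complete during stimulus plus delay, DR accuracy
#' is at least as high as RT accuracy under the same parameters. The
#' recorded response time is a motor latency measured from response-cue
#' onset, drawn independently of difficulty and censored at the response
#' window (`missed` beyond it); the cue onset time is carried in an extra
#' `cue_onset_s` column so the stimulus-onset convention is recoverable.
#'
#' @inheritParams simulate_ddm_dataset
#' @param motor_mean,motor_sd mean and sd (seconds) of the normal motor
#'   latency.
#' @return trial table data frame (with extra column `cue_onset_s`).
#' @export
simulate_dr_dataset <- function(design, params, seed, motor_mean = 0.25,
                                motor_sd = 0.04, dt = 5e-4) {
  stopifnot(inherits(design, "experiment_design"))
  if (design$dr_delay_s <= 0 || design$dr_response_window_s <= 0) {
    stop("DR delay and response window must be positive")
  }
  if (!any(design$runs == "DR")) stop("design contains no DR run")
  subj_par <- resolve_subject_params(params, design$n_subjects)
  cue_t <- design$stimulus_window_s + design$dr_delay_s
  set.seed(seed)
  out <- list()
  dr_runs <- sum(design$runs == "DR")
  for (j in seq_len(design$n_subjects)) {
    p <- subj_par[[j]]
    for (run in seq_len(dr_runs)) {
      lay <- run_trial_layout(design$trials_per_run)
      ups <- logical(nrow(lay))
      for (i in seq_len(nrow(lay))) {
        sim <- .ddm_sim_until_cue_cpp(1L, level_par(p$v, lay$level[i]),
                                      level_par(p$a, lay$level[i]), p$z_rel,
                                      p$sv, dt, cue_t)
        ups[i] <- isTRUE(sim$upper)
      }
      lat <- rnorm(nrow(lay), motor_mean, motor_sd)
      missed <- lat <= 0 | lat > design$dr_response_window_s
      other <- ifelse(lay$stimulus == "face", "house", "face")
      choice <- ifelse(missed, "missed", ifelse(ups, lay$stimulus, other))
      out[[length(out) + 1]] <- data.frame(
        subject = j, condition = "DR", coherence_level = lay$level,
        stimulus = lay$stimulus, choice = choice,
        correct = choice == lay$stimulus,
        rt = ifelse(missed, NA_real_, lat),
        cue_onset_s = cue_t)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate raw diffusion trials with a single parameter set
#'
#' Low-level helper around the Euler--Maruyama simulator: `n` first-passage
#' times and boundary indicators for one drift/boundary configuration,
#' without any task structure. Useful for Monte-Carlo checks against the
#' closed-form hit probability and the first-passage density.
#'
#' @param n number of trials.
#' @param params a [ddm_params()] with scalar `v` and `a`.
#' @param level which coherence level of `params` to use.
#' @param dt integration step, seconds.
#' @param max_t simulation horizon, seconds.
#' @return data frame with columns `rt` (including non-decision time; `NA`
#'   if not absorbed by `max_t`) and `upper` (logical).
#' @export
simulate_ddm_trials <- function(n, params, level = 1, dt = 5e-4, max_t = 10) {
  stopifnot(inherits(params, "ddm_params"))
  sim <- .ddm_sim_cpp(as.integer(n), level_par(params$v, level),
                      level_par(params$a, level), params$z_rel, params$t0,
                      params$sv, params$st, dt, max_t)
  data.frame(rt = sim$rt, upper = sim$upper)
}

#' Closed-form boundary-hit probability of the diffusion
#'
#' Probability that the diffusion with drift `v`, boundary separation `a`
#' and relative start `z_rel` (unit diffusion scale) is absorbed at the
#' upper boundary.
#'
#' @inheritParams ddm_params
#' @return probability of absorption at the upper boundary.
#' @examples
#' ddm_hit_probability(v = 1, a = 2) # (1 - exp(-2)) / (1 - exp(-4))
#' @export
ddm_hit_probability <- function(v, a, z_rel = 0.5) {
  if (a <= 0) stop("'a' must be positive")
  z <- z_rel * a
  if (abs(v) < 1e-12) return(z / a)
  (1 - exp(-2 * v * z)) / (1 - exp(-2 * v * a))
}
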