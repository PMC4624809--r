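#' Group-level generating parameters for the hierarchical behavior models
#'
#' Defines the generative structure that the hierarchical fitters assume:
#' per coherence level, subject accuracy means are drawn from a beta
#' distribution (group mean `acc_mean`, between-subject sd `acc_subject_sd`)
#' and subject mean response times from a gamma distribution (group mean
#' `rt_mean`, between-subject sd `rt_subject_sd`); trial response times are
#' gamma with trial-level sd `rt_trial_sd`, and per-subject correct counts
#' are binomial.
#'
#' Defaults are the study conditions: group accuracies 0.92/0.84/0.72/0.64
#' and group mean RTs 0.60/0.64/0.72/0.76 s across the four levels (easiest
#' first), between-subject sds of 0.04 (accuracy) and 0.10 s (RT), and a
#' trial-level RT sd of 0.15 s.
#'
#' @param acc_mean group mean accuracy per level, each in (0, 1).
#' @param acc_subject_sd between-subject sd of accuracy means (scalar or per
#'   level); its square must stay below `acc_mean * (1 - acc_mean)`.
#' @param rt_mean group mean response time per level, seconds.
#' @param rt_subject_sd between-subject sd of subject mean RTs, seconds.
#' @param rt_trial_sd trial-level RT sd around the subject mean, seconds.
#' @return object of class `hier_behavior_params`.
#' @export
hier_behavior_params <- function(acc_mean = c(0.92, 0.84, 0.72, 0.64),
                                 acc_subject_sd = 0.04,
                                 rt_mean = c(0.60, 0.64, 0.72, 0.76),
                                 rt_subject_sd = 0.10,
                                 rt_trial_sd = 0.15) {
  stopifnot(length(acc_mean) == length(rt_mean))
  if (any(acc_mean <= 0 | acc_mean >= 1)) stop("'acc_mean' must be in (0, 1)")
  if (any(rt_mean <= 0) || any(rt_subject_sd <= 0) || any(rt_trial_sd <= 0)) {
    stop("RT means and sds must be positive")
  }
  v <- rep_len(acc_subject_sd, length(acc_mean))^2
  if (any(v >= acc_mean * (1 - acc_mean))) {
    stop("accuracy variance must be below mean * (1 - mean) for a beta distribution")
  }
  structure(list(acc_mean = acc_mean,
                 acc_subject_sd = rep_len(acc_subject_sd, length(acc_mean)),
                 rt_mean = rt_mean,
                 rt_subject_sd = rep_len(rt_subject_sd, length(rt_mean)),
                 rt_trial_sd = rep_len(rt_trial_sd, length(rt_mean))),
            class = "hier_behavior_params")
}

#' Beta parameters from a mean and variance
#'
#' Maps a (mean, variance) pair to beta shape parameters via the
#' concentration `kappa = mean * (1 - mean) / var - 1`, `alpha = mean *
#' kappa`, `beta = (1 - mean) * kappa`. Pairs with `var >= mean * (1 -
#' mean)` are outside the beta family and rejected.
#'
#' @param mean mean in (0, 1).
#' @param var variance, `0 < var < mean * (1 - mean)`.
#' @return list with `alpha` and `beta`.
#' @export
beta_mean_var_to_ab <- function(mean, var) {
  if (any(mean <= 0 | mean >= 1)) stop("'mean' must be in (0, 1)")
  if (any(var <= 0)) stop("'var' must be positive")
  if (any(var >= mean * (1 - mean))) {
    stop("'var' must be below mean * (1 - mean)")
  }
  kappa <- mean * (1 - mean) / var - 1
  list(alpha = mean * kappa, beta = (1 - mean) * kappa)
}

#' Simulate behavioral trials directly from the hierarchical models
#'
#' Generates trial tables with exactly the structure assumed by
#' [fit_rt_model()] and [fit_accuracy_model()]: per level, subject accuracy
#' means drawn from the group beta, subject mean RTs from the group gamma,
#' then binomial correctness and gamma trial RTs. No censoring is applied
#' (the fitted models describe given responses, not misses).
#'
#' @param design an [experiment_design()]; determines the default number of
#'   trials per subject and level for the chosen condition.
#' @param group_params a [hier_behavior_params()].
#' @param seed integer seed.
#' @param condition label written in the `condition` column, `"RT"` or
#'   `"DR"`.
#' @param trials_per_level trials per subject and level; default: all trials
#'   of the `condition` runs divided evenly over the levels.
#' @return trial table data frame; empty (0 rows) if the design has zero
#'   subjects.
#' @examples
#' d <- experiment_design(n_subjects = 3)
#' tt <- simulate_hier_behavior(d, hier_behavior_params(), seed = 1)
#' aggregate(correct ~ coherence_level, tt, mean)
#' @export
simulate_hier_behavior <- function(design, group_params, seed,
                                   condition = "RT",
                                   trials_per_level = NULL) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(group_params, "hier_behavior_params"))
  condition <- match.arg(condition, c("RT", "DR"))
  gp <- group_params
  n_lev <- length(gp$acc_mean)
  if (is.null(trials_per_level)) {
    n_run <- sum(design$runs == condition)
    trials_per_level <- max(1L, round(n_run * design$trials_per_run / n_lev))
  }
  set.seed(seed)
  if (design$n_subjects == 0) {
    return(empty_trial_table())
  }
  out <- vector("list", design$n_subjects)
  for (j in seq_len(design$n_subjects)) {
    rows <- vector("list", n_lev)
    for (c in seq_len(n_lev)) {
      ab <- beta_mean_var_to_ab(gp$acc_mean[c], gp$acc_subject_sd[c]^2)
      theta <- rbeta(1, ab$alpha, ab$beta)
      sr <- gamma_shape_rate(gp$rt_mean[c], gp$rt_subject_sd[c])
      mu <- rgamma(1, shape = sr$shape, rate = sr$rate)
      correct <- rbinom(trials_per_level, 1, theta) == 1
      sr_t <- gamma_shape_rate(mu, gp$rt_trial_sd[c])
      rt <- rgamma(trials_per_level, shape = sr_t$shape, rate = sr_t$rate)
      stimulus <- rep_len(c("face", "house"), trials_per_level)
      choice <- ifelse(correct, stimulus,
                       ifelse(stimulus == "face", "house", "face"))
      rows[[c]] <- data.frame(subject = j, condition = condition,
                              coherence_level = c, stimulus = stimulus,
                              choice = choice, correct = correct, rt = rt)
    }
    out[[j]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_trial_table <- function() {
  data.frame(subject = integer(), condition = character(),
             coherence_level = integer(), stimulus = character(),
             choice = character(), correct = logical(), rt = numeric())
}
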