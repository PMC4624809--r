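#' Wiener first-passage-time density
#'
#' Density of the first-passage time at one boundary of a Wiener diffusion
#' with drift `v`, boundary separation `a`, relative start point `z_rel`
#' and unit diffusion scale. The drift-free kernel is evaluated with a
#' small-time or large-time series expansion, truncated so the absolute
#' error is below `precision` and switching automatically to whichever
#' representation needs fewer terms. Optionally integrates normally
#' distributed trial-to-trial drift (sd `sv`) in closed form.
#'
#' @param t decision time(s), seconds (non-positive times have density 0).
#' @param v drift rate.
#' @param a boundary separation (> 0).
#' @param z_rel relative start point in (0, 1).
#' @param boundary `"lower"` or `"upper"`; the upper boundary is evaluated
#'   through the reflection `(v, z_rel) -> (-v, 1 - z_rel)`.
#' @param sv trial-to-trial drift sd (>= 0).
#' @param precision series truncation error target.
#' @return density value(s).
#' @export
wfpt_density <- function(t, v, a, z_rel = 0.5, boundary = c("lower", "upper"),
                         sv = 0, precision = 1e-7) {
  boundary <- match.arg(boundary)
  .wfpt_density_cpp(as.numeric(t), v, a, z_rel, sv, precision,
                    boundary == "upper")
}

#' Drift-diffusion log-likelihood of a set of trials
#'
#' Sum of log first-passage densities at `rt - t0`, with drift variability
#' `sv` integrated in closed form and non-decision-time variability `st`
#' (uniform range) integrated by a midpoint rule. With `sv = st = 0` this
#' reduces exactly to a plain Wiener first-passage log-likelihood. Any
#' trial with zero density (e.g. `rt <= t0` when `st = 0`) makes the
#' result `-Inf`.
#'
#' @param rt response times, seconds.
#' @param upper logical: did the trial end at the upper boundary?
#' @param v,a,z_rel,sv,precision as in [wfpt_density()].
#' @param t0 non-decision time, seconds.
#' @param st non-decision-time range, seconds.
#' @param n_quad midpoint-rule nodes for the `st` integral.
#' @return log-likelihood (0 for an empty trial set).
#' @export
ddm_loglik <- function(rt, upper, v, a, z_rel = 0.5, t0 = 0, sv = 0, st = 0,
                       precision = 1e-7, n_quad = 3) {
  if (length(rt) == 0) return(0)
  stopifnot(length(rt) == length(upper))
  .ddm_loglik_cpp(as.numeric(rt), as.logical(upper), v, a, z_rel, t0, sv, st,
                  precision, as.integer(n_quad))
}

#' Model variants of the hierarchical drift diffusion model
#'
#' Four variants differing in which parameters vary across coherence
#' levels: `m1` lets both drift rate and boundary separation vary (the
#' full model), `m2` ignores difficulty entirely, `m3` varies only drift
#' rate, `m4` varies only boundary separation. All variants estimate
#' subject non-decision times and group-level inter-trial variabilities of
#' drift (`sv`) and non-decision time (`st`); the start point is fixed at
#' `a/2` and the diffusion scale at 1.
#'
#' @param model `"m1"`, `"m2"`, `"m3"` or `"m4"`.
#' @return object of class `ddm_model_spec`.
#' @export
ddm_model_spec <- function(model = c("m1", "m2", "m3", "m4")) {
  model <- match.arg(model)
  vary <- switch(model,
                 m1 = c(v = TRUE, a = TRUE),
                 m2 = c(v = FALSE, a = FALSE),
                 m3 = c(v = TRUE, a = FALSE),
                 m4 = c(v = FALSE, a = TRUE))
  structure(list(model = model, vary_v = vary[["v"]], vary_a = vary[["a"]]),
            class = "ddm_model_spec")
}

ddm_prior_default <- function() {
  list(mu_v_mean = 0, mu_v_sd = 5,
       sd_v_lo = 0.01, sd_v_hi = 5,
       mu_log_a_mean = 0, mu_log_a_sd = 1.5,
       sd_log_a_lo = 0.01, sd_log_a_hi = 2,
       mu_log_t_mean = -1.2, mu_log_t_sd = 1.5,
       sd_log_t_lo = 0.01, sd_log_t_hi = 2,
       sv_hi = 3, st_hi = 0.25)
}

ddm_data_from_trials <- function(trials) {
  stopifnot(is.data.frame(trials))
  if (any(trials$condition != "RT")) {
    stop("the drift diffusion model assumes responses at boundary crossing; ",
         "delayed-response (DR) trials cannot be fit")
  }
  tt <- trials[trials$choice != "missed" & !is.na(trials$rt), ]
  subs <- sort(unique(tt$subject))
  levs <- sort(unique(tt$coherence_level))
  if (length(subs) < 2) stop("need at least 2 subjects")
  list(rt = as.numeric(tt$rt),
       upper = as.logical(tt$correct),
       subj = match(tt$subject, subs),
       lev = match(tt$coherence_level, levs),
       subjects = subs, levels = levs,
       J = length(subs), C = length(levs))
}

#' Fit the hierarchical drift diffusion model
#'
#' Hierarchical Bayesian estimation from reaction-time-condition trials.
#' Subject drift rates follow a normal group distribution per level (when
#' varying); boundary separations and non-decision times are log-normal.
#' Inter-trial variabilities `sv` and `st` are estimated at the group
#' level only. Sampling is Metropolis-within-Gibbs with adaptive
#' random-walk proposals (adaptation restricted to burn-in) and conjugate
#' draws for group means; the likelihood is the Wiener first-passage
#' density of [ddm_loglik()].
#'
#' Group parameter names: `v_mean[c]`, `v_sd[c]`, `log_a_mean[c]`,
#' `log_a_sd[c]` (indices dropped when the parameter does not vary by
#' level), `log_t_mean`, `log_t_sd`, `sv`, `st`. Subject parameters:
#' `v[j,c]`, `log_a[j,c]`, `log_t[j]`. Deviance samples (-2 log L) are
#' stored for DIC computation.
#'
#' @param trials RT-condition trial table (DR trials raise an error).
#' @param spec a [ddm_model_spec()].
#' @param mcmc_cfg an [mcmc_config()].
#' @param seed integer seed; fits are fully reproducible given the seed.
#' @param precision wfpt series truncation error target.
#' @param n_quad midpoint nodes for the `st` integral.
#' @param prior list of prior constants (see `accumaint:::ddm_prior_default`).
#' @return object of class `ddm_posterior` (a [posterior_chains()] with
#'   deviance samples and the data attached).
#' @export
fit_hddm <- function(trials, spec = ddm_model_spec("m1"),
                     mcmc_cfg = mcmc_config(), seed = 1, precision = 1e-7,
                     n_quad = 3, prior = ddm_prior_default()) {
  stopifnot(inherits(spec, "ddm_model_spec"))
  dat <- ddm_data_from_trials(trials)
  J <- dat$J
  C <- dat$C
  Lv <- if (spec$vary_v) C else 1
  La <- if (spec$vary_a) C else 1

  # data-driven starting values: signed accuracy for drift, boundary near
  # 1.4, non-decision time below each subject's fastest response
  acc <- matrix(0.5, J, C)
  minrt <- numeric(J)
  for (j in seq_len(J)) {
    for (c in seq_len(C)) {
      sel <- dat$subj == j & dat$lev == c
      if (any(sel)) acc[j, c] <- mean(dat$upper[sel])
    }
    minrt[j] <- min(dat$rt[dat$subj == j])
  }
  v0_full <- 2 * (2 * acc - 1)

  chains_group <- vector("list", mcmc_cfg$chains)
  chains_subj <- vector("list", mcmc_cfg$chains)
  chains_dev <- vector("list", mcmc_cfg$chains)
  for (k in seq_len(mcmc_cfg$chains)) {
    set.seed(seed * 100 + k)
    v0 <- if (spec$vary_v) v0_full else rowMeans(v0_full)
    v0 <- matrix(v0, J, Lv) + matrix(rnorm(J * Lv, 0, 0.2), J, Lv)
    la0 <- matrix(log(1.4), J, La) + matrix(rnorm(J * La, 0, 0.1), J, La)
    lt0 <- log(pmax(0.8 * minrt, 0.05)) + rnorm(J, 0, 0.05)
    init <- list(v = v0, log_a = la0, log_t = lt0,
                 mu_v = colMeans(v0), sd_v = rep(0.5, Lv),
                 mu_log_a = colMeans(la0), sd_log_a = rep(0.2, La),
                 mu_log_t = mean(lt0), sd_log_t = 0.2,
                 sv = runif(1, 0.05, 0.3), st = runif(1, 0.005, 0.02))
    res <- .hddm_mcmc_cpp(dat$rt, dat$upper, dat$subj, dat$lev, J, C,
                          spec$vary_v, spec$vary_a, mcmc_cfg$burnin,
                          mcmc_cfg$samples, precision, as.integer(n_quad),
                          init, prior)
    chains_group[[k]] <- res$group
    chains_subj[[k]] <- res$subject
    chains_dev[[k]] <- res$deviance
  }

  idx <- function(base, L) {
    if (L == 1) base else sprintf("%s[%d]", base, seq_len(L))
  }
  group_names <- c(idx("v_mean", Lv), idx("v_sd", Lv),
                   idx("log_a_mean", La), idx("log_a_sd", La),
                   "log_t_mean", "log_t_sd", "sv", "st")
  subj_names <- c(
    as.vector(outer(seq_len(J), seq_len(Lv),
                    function(j, l) sprintf("v[%d,%d]", j, l))),
    as.vector(outer(seq_len(J), seq_len(La),
                    function(j, l) sprintf("log_a[%d,%d]", j, l))),
    sprintf("log_t[%d]", seq_len(J)))

  all_names <- c(group_names, subj_names)
  samples <- setNames(vector("list", length(all_names)), all_names)
  for (i in seq_along(group_names)) {
    samples[[group_names[i]]] <-
      do.call(rbind, lapply(chains_group, function(m) m[, i]))
  }
  for (i in seq_along(subj_names)) {
    samples[[subj_names[i]]] <-
      do.call(rbind, lapply(chains_subj, function(m) m[, i]))
  }
  post <- posterior_chains(samples, burnin = mcmc_cfg$burnin,
                           thin = mcmc_cfg$thin, seed = seed,
                           group_params = group_names)
  post$deviance <- do.call(rbind, chains_dev)
  post$spec <- spec
  post$data <- dat
  post$precision <- precision
  post$n_quad <- as.integer(n_quad)
  class(post) <- c("ddm_posterior", class(post))
  post
}

# posterior means of every sampled parameter, as plain vectors/matrices
ddm_posterior_means <- function(post) {
  dat <- post$data
  J <- dat$J
  C <- dat$C
  Lv <- if (post$spec$vary_v) C else 1
  La <- if (post$spec$vary_a) C else 1
  pm <- function(p) mean(chain_samples(post, p, pooled = TRUE))
  v <- matrix(0, J, Lv)
  la <- matrix(0, J, La)
  for (l in seq_len(Lv)) for (j in seq_len(J)) {
    v[j, l] <- pm(sprintf("v[%d,%d]", j, l))
  }
  for (l in seq_len(La)) for (j in seq_len(J)) {
    la[j, l] <- pm(sprintf("log_a[%d,%d]", j, l))
  }
  lt <- vapply(seq_len(J), function(j) pm(sprintf("log_t[%d]", j)), numeric(1))
  list(v = v, log_a = la, log_t = lt, sv = pm("sv"), st = pm("st"))
}

ddm_deviance_at <- function(post, pars) {
  dat <- post$data
  C <- dat$C
  Lv <- ncol(pars$v)
  La <- ncol(pars$log_a)
  ll <- 0
  for (j in seq_len(dat$J)) {
    for (c in seq_len(C)) {
      sel <- dat$subj == j & dat$lev == c
      if (!any(sel)) next
      lv <- if (Lv == 1) 1 else c
      la <- if (La == 1) 1 else c
      ll <- ll + .ddm_loglik_cpp(dat$rt[sel], dat$upper[sel],
                                 pars$v[j, lv], exp(pars$log_a[j, la]), 0.5,
                                 exp(pars$log_t[j]), pars$sv, pars$st,
                                 post$precision, post$n_quad)
    }
  }
  -2 * ll
}

#' Deviance information criterion of a fitted DDM
#'
#' `DIC = Dbar + pD` with `Dbar` the posterior mean deviance and `pD =
#' Dbar - D(posterior means)` (plug-in effective number of parameters).
#' Lower values indicate better fit.
#'
#' @param posterior a `ddm_posterior` from [fit_hddm()].
#' @return list of class `dic_result` with `dic`, `mean_deviance`, `pd`.
#' @export
dic <- function(posterior) {
  stopifnot(inherits(posterior, "ddm_posterior"))
  dev <- as.vector(posterior$deviance)
  if (length(dev) < 100) stop("need at least 100 deviance samples for DIC")
  dbar <- mean(dev)
  dhat <- ddm_deviance_at(posterior, ddm_posterior_means(posterior))
  structure(list(dic = dbar + (dbar - dhat), mean_deviance = dbar,
                 pd = dbar - dhat), class = "dic_result")
}

#' @export
print.dic_result <- function(x, ...) {
  cat(sprintf("DIC %.1f (mean deviance %.1f, pD %.1f)\n",
              x$dic, x$mean_deviance, x$pd))
  invisible(x)
}

#' Compare DDM variants by DIC
#'
#' @param posteriors named list of `ddm_posterior` objects.
#' @return data frame ranked by DIC (best first).
#' @export
dic_table <- function(posteriors) {
  rows <- lapply(names(posteriors), function(nm) {
    d <- dic(posteriors[[nm]])
    data.frame(model = nm, dic = d$dic, mean_deviance = d$mean_deviance,
               pd = d$pd)
  })
  out <- do.call(rbind, rows)
  out[order(out$dic), ]
}

#' Posterior predictive datasets from a fitted DDM
#'
#' Draws parameter vectors from the posterior and simulates datasets with
#' the same subject x level trial counts as the fitted data. Error
#' responses are coded with negative response times, the usual convention
#' for overlaying correct and error RT distributions.
#'
#' @param posterior a `ddm_posterior`.
#' @param n_draws number of simulated datasets (0 gives an empty table).
#' @param seed integer seed.
#' @param dt simulation step, seconds.
#' @return data frame with columns `draw`, `subject`, `coherence_level`,
#'   `correct`, `rt` (signed).
#' @export
posterior_predictive <- function(posterior, n_draws = 20, seed = 1,
                                 dt = 1e-3) {
  stopifnot(inherits(posterior, "ddm_posterior"))
  dat <- posterior$data
  C <- dat$C
  Lv <- if (posterior$spec$vary_v) C else 1
  La <- if (posterior$spec$vary_a) C else 1
  n_chain <- nrow(posterior$samples[[1]])
  n_iter <- ncol(posterior$samples[[1]])
  set.seed(seed)
  out <- list()
  for (d in seq_len(n_draws)) {
    ch <- sample.int(n_chain, 1)
    it <- sample.int(n_iter, 1)
    gv <- function(p) posterior$samples[[p]][ch, it]
    sv <- gv("sv")
    st <- gv("st")
    for (j in seq_len(dat$J)) {
      t0 <- exp(gv(sprintf("log_t[%d]", j)))
      for (c in seq_len(C)) {
        n_cell <- sum(dat$subj == j & dat$lev == c)
        if (n_cell == 0) next
        v <- gv(sprintf("v[%d,%d]", j, if (Lv == 1) 1 else c))
        a <- exp(gv(sprintf("log_a[%d,%d]", j, if (La == 1) 1 else c)))
        sim <- .ddm_sim_cpp(n_cell, v, a, 0.5, t0, sv, st, dt, 10)
        ok <- !is.na(sim$rt)
        out[[length(out) + 1]] <- data.frame(
          draw = d, subject = dat$subjects[j],
          coherence_level = dat$levels[c],
          correct = sim$upper[ok],
          rt = ifelse(sim$upper[ok], sim$rt[ok], -sim$rt[ok]))
      }
    }
  }
  if (!length(out)) {
    return(data.frame(draw = integer(), subject = integer(),
                      coherence_level = integer(), correct = logical(),
                      rt = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
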