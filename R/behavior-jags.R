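#' MCMC configuration
#'
#' @param chains number of chains (>= 2 for convergence diagnostics).
#' @param samples kept samples per chain after burn-in.
#' @param burnin discarded iterations per chain (includes the sampler's
#'   adaptation phase).
#' @param thin thinning interval.
#' @return list of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 3, samples = 5000, burnin = 2000, thin = 1) {
  if (chains < 1 || samples < 1 || thin < 1 || burnin < 0) {
    stop("invalid MCMC configuration")
  }
  if (burnin == 0) {
    warning("running with zero burn-in; early samples may not have converged")
  }
  structure(list(chains = as.integer(chains), samples = as.integer(samples),
                 burnin = as.integer(burnin), thin = as.integer(thin)),
            class = "mcmc_config")
}

# Per-cell (level x subject) counts and sufficient statistics from a trial
# table, excluding missed trials. Errors name the offending subject x level.
behavior_cells <- function(trials, condition, need_rt) {
  stopifnot(is.data.frame(trials),
            all(c("subject", "condition", "coherence_level", "choice",
                  "correct", "rt") %in% names(trials)))
  tt <- trials[trials$condition == condition & trials$choice != "missed", ]
  if (need_rt) tt <- tt[!is.na(tt$rt), ]
  subs <- sort(unique(tt$subject))
  levs <- sort(unique(tt$coherence_level))
  if (length(subs) < 2) stop("need at least 2 subjects")
  J <- length(subs)
  C <- length(levs)
  n <- z <- S <- L <- matrix(0, C, J)
  for (ci in seq_len(C)) {
    for (ji in seq_len(J)) {
      cell <- tt[tt$subject == subs[ji] & tt$coherence_level == levs[ci], ]
      if (nrow(cell) < 2) {
        stop(sprintf("fewer than 2 usable trials for subject %s, level %s",
                     subs[ji], levs[ci]))
      }
      n[ci, ji] <- nrow(cell)
      z[ci, ji] <- sum(cell$correct)
      if (need_rt) {
        S[ci, ji] <- sum(cell$rt)
        L[ci, ji] <- sum(log(cell$rt))
      }
    }
  }
  list(J = J, C = C, subjects = subs, levels = levs, n = n, z = z, S = S, L = L,
       trials = tt)
}

rt_model_string <- "
model {
  for (c in 1:C) {
    m_mu[c] ~ dunif(0.01, 30)
    s_mu[c] ~ dunif(0.01, 30)
    m_s2[c] ~ dunif(0.01, 30)
    s_s2[c] ~ dunif(0.01, 30)
    for (j in 1:J) {
      mu[c,j] ~ dgamma(pow(m_mu[c], 2) / pow(s_mu[c], 2), m_mu[c] / pow(s_mu[c], 2))
      s2[c,j] ~ dgamma(pow(m_s2[c], 2) / pow(s_s2[c], 2), m_s2[c] / pow(s_s2[c], 2))
      alpha[c,j] <- pow(mu[c,j], 2) / s2[c,j]
      beta[c,j] <- mu[c,j] / s2[c,j]
      # gamma likelihood through its sufficient statistics (zeros trick)
      phi[c,j] <- Cbig - (n[c,j] * (alpha[c,j] * log(beta[c,j]) - loggam(alpha[c,j]))
                  + (alpha[c,j] - 1) * L[c,j] - beta[c,j] * S[c,j])
      zeros[c,j] ~ dpois(phi[c,j])
    }
  }
}"

# Subject-level accuracies are conjugate given (omega, kappa), so they are
# integrated out analytically and the count likelihood is the beta-binomial
# marginal (zeros trick; the binomial coefficient is constant and dropped).
# Subject draws are recovered after sampling from their conjugate beta
# conditionals, which leaves the joint posterior unchanged and removes the
# omega/kappa/theta funnel from the sampler.
acc_model_string <- "
model {
  for (c in 1:C) {
    omega[c] ~ dbeta(1, 1) T(0.0001, 0.9999)
    m_k[c] ~ dunif(0.01, 30)
    s_k[c] ~ dunif(0.01, 30)
    kappa[c] ~ dgamma(pow(m_k[c], 2) / pow(s_k[c], 2), m_k[c] / pow(s_k[c], 2))
    vth[c] <- omega[c] * (1 - omega[c]) / (kappa[c] + 1)
    for (j in 1:J) {
      a_par[c,j] <- omega[c] * kappa[c]
      b_par[c,j] <- (1 - omega[c]) * kappa[c]
      phi[c,j] <- Cbig - (loggam(z[c,j] + a_par[c,j]) + loggam(N[c,j] - z[c,j] + b_par[c,j])
                  - loggam(N[c,j] + kappa[c]) - loggam(a_par[c,j])
                  - loggam(b_par[c,j]) + loggam(kappa[c]))
      zeros[c,j] ~ dpois(phi[c,j])
    }
  }
}"

run_jags <- function(model_string, data, inits, monitors, cfg) {
  m <- rjags::jags.model(textConnection(model_string), data = data,
                         inits = inits, n.chains = cfg$chains,
                         n.adapt = min(1000L, cfg$burnin), quiet = TRUE)
  rest <- cfg$burnin - min(1000L, cfg$burnin)
  if (rest > 0) update(m, rest, progress.bar = "none")
  coda::as.mcmc.list(
    rjags::coda.samples(m, monitors, n.iter = cfg$samples * cfg$thin,
                        thin = cfg$thin, progress.bar = "none"))
}

# mcmc.list -> named list of chains x samples matrices, renamed via `rename`
# (a function applied to JAGS variable names).
mcmc_to_chains <- function(mcl, rename = identity) {
  pars <- colnames(mcl[[1]])
  samples <- lapply(pars, function(p) {
    do.call(rbind, lapply(mcl, function(ch) as.numeric(ch[, p])))
  })
  names(samples) <- vapply(pars, rename, character(1))
  samples
}

#' Fit the hierarchical gamma response-time model
#'
#' Per coherence level, subject mean RTs are drawn from a group gamma
#' distribution and subject RT variances from another group gamma; trial
#' RTs follow a gamma likelihood with shape `mu^2/var` and rate `mu/var`.
#' Every gamma is parameterized by a mean and sd with uniform(0.01, 30)
#' hyperpriors. Fitting is by Gibbs sampling (JAGS); the trial likelihood
#' is evaluated through per-cell sufficient statistics, which leaves the
#' posterior unchanged. Missed trials are excluded before fitting.
#'
#' Group-level parameters are reported as `rt_mean[c]` (group mean of
#' subject mean RTs; the headline parameter), `rt_mean_sd[c]`,
#' `rt_var_mean[c]` and `rt_var_sd[c]`; subject means as
#' `rt_subj_mean[c,j]`.
#'
#' @param trials trial table data frame.
#' @param condition which condition's trials to fit (`"RT"` or `"DR"`).
#' @param mcmc_cfg an [mcmc_config()].
#' @param seed integer seed controlling initial values and the JAGS RNG.
#' @return a [posterior_chains()].
#' @export
fit_rt_model <- function(trials, condition = "RT", mcmc_cfg = mcmc_config(),
                         seed = 1) {
  cells <- behavior_cells(trials, condition, need_rt = TRUE)
  data <- list(C = cells$C, J = cells$J, n = cells$n, S = cells$S,
               L = cells$L, zeros = matrix(0, cells$C, cells$J), Cbig = 1e6)
  cell_mean <- cells$S / cells$n
  lev_mean <- rowMeans(cell_mean)
  set.seed(seed)
  inits <- lapply(seq_len(mcmc_cfg$chains), function(k) {
    jit <- function(x) x * runif(length(x), 0.85, 1.15)
    list(m_mu = pmax(jit(lev_mean), 0.02),
         s_mu = runif(cells$C, 0.05, 0.3),
         m_s2 = runif(cells$C, 0.02, 0.1),
         s_s2 = runif(cells$C, 0.02, 0.1),
         mu = pmax(jit(cell_mean), 0.02),
         s2 = matrix(runif(cells$C * cells$J, 0.01, 0.05), cells$C, cells$J),
         .RNG.name = "base::Mersenne-Twister",
         .RNG.seed = seed * 100 + k)
  })
  mcl <- run_jags(rt_model_string, data, inits,
                  c("m_mu", "s_mu", "m_s2", "s_s2", "mu"), mcmc_cfg)
  ren <- function(p) {
    p <- sub("^m_mu", "rt_mean", p)
    p <- sub("^s_mu", "rt_mean_sd", p)
    p <- sub("^m_s2", "rt_var_mean", p)
    p <- sub("^s_s2", "rt_var_sd", p)
    sub("^mu", "rt_subj_mean", p)
  }
  samples <- mcmc_to_chains(mcl, ren)
  group <- grep("^rt_(mean|mean_sd|var_mean|var_sd)\\[", names(samples),
                value = TRUE)
  posterior_chains(samples, burnin = mcmc_cfg$burnin, thin = mcmc_cfg$thin,
                   seed = seed, group_params = group)
}

#' Fit the hierarchical beta-binomial accuracy model
#'
#' Per coherence level, subject accuracy means are drawn from a beta
#' distribution with group mean `omega[c]` (uniform, i.e. beta(1, 1),
#' prior) and concentration `kappa[c]` with a gamma prior whose mean and
#' sd have uniform(0.01, 30) hyperpriors; the implied group variance
#' `omega (1 - omega) / (kappa + 1)` is reported as a derived quantity
#' and is automatically inside the beta family's admissible range.
#' Correct counts are binomial. Fitting is by Gibbs sampling (JAGS);
#' missed trials are excluded.
#'
#' Group-level parameters are reported as `acc_mean[c]` (the headline
#' group accuracy), `acc_conc[c]`, `acc_conc_hyper_mean[c]` and
#' `acc_conc_hyper_sd[c]`, with the derived `acc_var[c]`; subject means
#' as `acc_subj[c,j]`.
#'
#' @inheritParams fit_rt_model
#' @param counts optional precomputed count table (data frame with columns
#'   `subject`, `coherence_level`, `z`, `N`) used instead of `trials`.
#' @return a [posterior_chains()].
#' @export
fit_accuracy_model <- function(trials = NULL, condition = "RT",
                               mcmc_cfg = mcmc_config(), seed = 1,
                               counts = NULL) {
  if (is.null(counts)) {
    cells <- behavior_cells(trials, condition, need_rt = FALSE)
    zmat <- cells$z
    Nmat <- cells$n
    C <- cells$C
    J <- cells$J
  } else {
    stopifnot(all(c("subject", "coherence_level", "z", "N") %in% names(counts)))
    if (any(counts$z > counts$N)) stop("correct count z exceeds trial count N")
    if (any(counts$z < 0 | counts$N < 1)) stop("invalid counts")
    subs <- sort(unique(counts$subject))
    levs <- sort(unique(counts$coherence_level))
    if (length(subs) < 2) stop("need at least 2 subjects")
    C <- length(levs)
    J <- length(subs)
    zmat <- Nmat <- matrix(0, C, J)
    for (i in seq_len(nrow(counts))) {
      ci <- match(counts$coherence_level[i], levs)
      ji <- match(counts$subject[i], subs)
      zmat[ci, ji] <- counts$z[i]
      Nmat[ci, ji] <- counts$N[i]
    }
  }
  data <- list(C = C, J = J, z = zmat, N = Nmat,
               zeros = matrix(0, C, J), Cbig = 100)
  emp <- pmin(pmax((zmat + 1) / (Nmat + 2), 0.03), 0.97)
  set.seed(seed)
  inits <- lapply(seq_len(mcmc_cfg$chains), function(k) {
    om <- pmin(pmax(rowMeans(emp) * runif(C, 0.9, 1.1), 0.05), 0.93)
    list(omega = om,
         m_k = runif(C, 5, 25),
         s_k = runif(C, 5, 25),
         kappa = runif(C, 10, 60),
         .RNG.name = "base::Mersenne-Twister",
         .RNG.seed = seed * 100 + k)
  })
  mcl <- run_jags(acc_model_string, data, inits,
                  c("omega", "kappa", "vth", "m_k", "s_k"), mcmc_cfg)
  ren <- function(p) {
    p <- sub("^omega", "acc_mean", p)
    p <- sub("^kappa", "acc_conc", p)
    p <- sub("^vth", "acc_var", p)
    p <- sub("^m_k", "acc_conc_hyper_mean", p)
    sub("^s_k", "acc_conc_hyper_sd", p)
  }
  samples <- mcmc_to_chains(mcl, ren)
  # subject accuracies: conjugate beta conditional draws per kept sample
  n_ch <- nrow(samples[[1]])
  n_it <- ncol(samples[[1]])
  for (ci in seq_len(C)) {
    om <- samples[[sprintf("acc_mean[%d]", ci)]]
    ka <- samples[[sprintf("acc_conc[%d]", ci)]]
    for (ji in seq_len(J)) {
      draws <- rbeta(n_ch * n_it, zmat[ci, ji] + om * ka,
                     Nmat[ci, ji] - zmat[ci, ji] + (1 - om) * ka)
      samples[[sprintf("acc_subj[%d,%d]", ci, ji)]] <-
        matrix(draws, n_ch, n_it)
    }
  }
  group <- grep("^acc_(mean|conc|conc_hyper_mean|conc_hyper_sd)\\[",
                names(samples), value = TRUE)
  posterior_chains(samples, burnin = mcmc_cfg$burnin, thin = mcmc_cfg$thin,
                   seed = seed, group_params = group)
}
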