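#' Gamma shape and rate from a mean and standard deviation
#'
#' All gamma distributions in the hierarchical behavior models are
#' parameterized by shape and rate obtained by transforming a mean and a
#' standard deviation: `shape = mean^2 / sd^2`, `rate = mean / sd^2`.
#'
#' @param mean positive mean.
#' @param sd positive standard deviation.
#' @return list with `shape` and `rate`.
#' @examples
#' gamma_shape_rate(2, 1)      # shape 4, rate 2
#' gamma_shape_rate(0.6, 0.15) # shape 16, rate 26.67
#' @export
gamma_shape_rate <- function(mean, sd) {
  if (any(mean <= 0) || any(sd <= 0)) stop("'mean' and 'sd' must be positive")
  list(shape = mean^2 / sd^2, rate = mean / sd^2)
}

#' Posterior chains container
#'
#' Holds labeled MCMC samples: one `chains x samples` matrix per parameter,
#' plus metadata (burn-in, thinning, seed) and the names of the group-level
#' parameters used for convergence reporting.
#'
#' @param samples named list; each element a numeric matrix with one row per
#'   chain and one column per kept sample (equal lengths).
#' @param burnin,thin,seed sampler metadata.
#' @param group_params character vector naming the group-level parameters.
#' @return object of class `posterior_chains`.
#' @export
posterior_chains <- function(samples, burnin = NA_integer_, thin = 1L,
                             seed = NA_integer_, group_params = character()) {
  stopifnot(is.list(samples), length(samples) > 0, !is.null(names(samples)))
  ncols <- vapply(samples, ncol, integer(1))
  if (length(unique(ncols)) != 1) stop("all parameters must have equal chain lengths")
  structure(list(samples = samples, burnin = burnin, thin = thin, seed = seed,
                 group_params = group_params),
            class = "posterior_chains")
}

#' @export
print.posterior_chains <- function(x, ...) {
  m <- x$samples[[1]]
  cat(sprintf("posterior_chains: %d parameters, %d chains x %d samples\n",
              length(x$samples), nrow(m), ncol(m)))
  cat("  parameters:", paste(head(names(x$samples), 8), collapse = ", "),
      if (length(x$samples) > 8) "..." else "", "\n")
  invisible(x)
}

#' Extract one parameter's chains
#'
#' @param x a `posterior_chains`.
#' @param param parameter name.
#' @param pooled if `TRUE`, return one vector with the chains concatenated
#'   in chain order; otherwise the `chains x samples` matrix.
#' @return matrix or numeric vector.
#' @export
chain_samples <- function(x, param, pooled = FALSE) {
  stopifnot(inherits(x, "posterior_chains"))
  if (!param %in% names(x$samples)) {
    stop(sprintf("unknown parameter '%s'", param))
  }
  m <- x$samples[[param]]
  if (pooled) as.vector(t(m)) else m
}

#' Grouped chain: sample-by-sample mean of several chains
#'
#' When several parameters are combined (for example the two easiest
#' coherence levels into "easy"), the combination is a grouped chain: the
#' element-wise mean of the constituent sample arrays, with equal weight.
#'
#' @param chains list of equal-length numeric vectors (or a single vector).
#' @return numeric vector of the same length.
#' @examples
#' group_chain(list(c(1, 2), c(3, 4))) # 2 3
#' @export
group_chain <- function(chains) {
  if (is.numeric(chains)) return(chains)
  stopifnot(is.list(chains), length(chains) >= 1)
  n <- unique(vapply(chains, length, integer(1)))
  if (length(n) != 1) stop("all chains must have equal length")
  Reduce(`+`, chains) / length(chains)
}

#' Grouped chain over parameters of a fitted model
#'
#' Convenience wrapper: pools each named parameter across chains and
#' returns the grouped (equal-weight, sample-by-sample mean) chain.
#'
#' @param x a `posterior_chains`.
#' @param params parameter names to combine.
#' @return numeric vector (pooled across chains).
#' @export
grouped_parameter_chain <- function(x, params) {
  group_chain(lapply(params, function(p) chain_samples(x, p, pooled = TRUE)))
}

#' Posterior probability that one chain exceeds another
#'
#' Fraction of paired posterior samples for which `a - b` is strictly
#' greater than zero: the posterior probability that the first quantity is
#' larger, reported in place of a classical test.
#'
#' @param chain_a,chain_b equal-length sample vectors (paired by index).
#' @return probability in `[0, 1]`.
#' @examples
#' prob_greater(c(1, 2, 3), c(0, 0, 0)) # 1
#' @export
prob_greater <- function(chain_a, chain_b) {
  if (length(chain_a) != length(chain_b)) stop("chains must have equal length")
  mean(chain_a - chain_b > 0)
}

#' Highest density interval of posterior samples
#'
#' The narrowest contiguous interval containing `ceiling(mass * n)` of the
#' sorted samples; ties are broken by the first narrowest window in sorted
#' order.
#'
#' @param samples numeric vector with at least 20 samples.
#' @param mass interval mass in (0, 1); default 0.95.
#' @return numeric vector `c(lower, upper)`.
#' @export
hdi <- function(samples, mass = 0.95) {
  if (length(samples) < 20) stop("need at least 20 samples for an HDI")
  if (mass <= 0 || mass >= 1) stop("'mass' must be in (0, 1)")
  s <- sort(samples)
  n <- length(s)
  k <- ceiling(mass * n)
  if (k >= n) return(c(s[1], s[n]))
  widths <- s[k:n] - s[1:(n - k + 1)]
  i <- which.min(widths)
  c(s[i], s[i + k - 1])
}

#' Gelman--Rubin potential scale reduction factor
#'
#' Classic split-free R-hat: with m chains of length n, within-chain
#' variance W (mean of chain variances), between-chain variance B (n times
#' the variance of chain means), pooled estimate `V = (n-1)/n W + B/n`, and
#' `Rhat = sqrt(V / W)`. Values near 1 indicate convergence.
#'
#' @param chains a `chains x samples` matrix, a list of equal-length
#'   vectors, or a `posterior_chains` (then one R-hat per parameter is
#'   returned, restricted to `params` if given).
#' @param params optional parameter names (for `posterior_chains` input).
#' @return a single R-hat, or a named vector for `posterior_chains` input.
#' @export
gelman_rubin <- function(chains, params = NULL) {
  if (inherits(chains, "posterior_chains")) {
    if (is.null(params)) params <- names(chains$samples)
    return(vapply(params, function(p) gelman_rubin(chains$samples[[p]]),
                  numeric(1)))
  }
  if (is.list(chains)) {
    n <- unique(vapply(chains, length, integer(1)))
    if (length(n) != 1) stop("all chains must have equal length")
    chains <- do.call(rbind, chains)
  }
  m <- nrow(chains)
  n <- ncol(chains)
  if (m < 2) stop("Gelman-Rubin diagnostic needs at least 2 chains")
  if (n < 10) stop("chains too short for the Gelman-Rubin diagnostic")
  W <- mean(apply(chains, 1, var))
  if (W <= 0) stop("zero within-chain variance")
  B_over_n <- var(rowMeans(chains))
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

#' Posterior summary table
#'
#' Posterior mean, 95% HDI and R-hat for each (or the named) parameters of
#' a fit.
#'
#' @param x a `posterior_chains`.
#' @param params parameter names; default: the group-level parameters.
#' @param mass HDI mass.
#' @return data frame with columns `parameter`, `mean`, `hdi_low`,
#'   `hdi_high`, `rhat`.
#' @export
posterior_summary <- function(x, params = NULL, mass = 0.95) {
  stopifnot(inherits(x, "posterior_chains"))
  if (is.null(params)) {
    params <- if (length(x$group_params)) x$group_params else names(x$samples)
  }
  rows <- lapply(params, function(p) {
    pooled <- chain_samples(x, p, pooled = TRUE)
    iv <- hdi(pooled, mass)
    rhat <- if (nrow(x$samples[[p]]) >= 2) gelman_rubin(x$samples[[p]]) else NA_real_
    data.frame(parameter = p, mean = mean(pooled), hdi_low = iv[1],
               hdi_high = iv[2], rhat = rhat)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write chains as a flat CSV
#'
#' Long format `parameter,chain,iter,value`, the canonical on-disk form for
#' fitted chains.
#'
#' @param x a `posterior_chains`.
#' @param path file path.
#' @export
write_chains_csv <- function(x, path) {
  stopifnot(inherits(x, "posterior_chains"))
  rows <- lapply(names(x$samples), function(p) {
    m <- x$samples[[p]]
    data.frame(parameter = p,
               chain = rep(seq_len(nrow(m)), each = ncol(m)),
               iter = rep(seq_len(ncol(m)), nrow(m)),
               value = as.vector(t(m)))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
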