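#' Firing-profile parameters of a hypothetical decision neuron
#'
#' A decision neuron ramps linearly from a baseline firing rate `BL` to a
#' decision threshold `T` over a difficulty-dependent time-to-threshold.
#' Two response mechanisms are distinguished: an accumulate-and-maintain
#' neuron keeps firing at threshold until the response cue (the pattern
#' recorded in monkey LIP), whereas an accumulate-only neuron returns to
#' baseline as soon as the boundary is reached.
#'
#' @param baseline baseline firing rate, Hz.
#' @param threshold decision threshold firing rate, Hz (> baseline).
#' @param time_to_threshold named numeric `c(easy = ..., hard = ...)`,
#'   seconds; hard must exceed easy.
#' @param maintenance_until time of the response cue in the DR condition,
#'   seconds from stimulus onset.
#' @param mode `"accumulate_maintain"` or `"accumulate_only"`.
#' @param decay_tau optional exponential decay time constant after the
#'   ramp/maintenance ends; `0` means an instantaneous return to baseline.
#' @return object of class `firing_params`.
#' @export
firing_params <- function(baseline = 5, threshold = 50,
                          time_to_threshold = c(easy = 0.4, hard = 0.8),
                          maintenance_until = 1.5,
                          mode = c("accumulate_maintain", "accumulate_only"),
                          decay_tau = 0) {
  mode <- match.arg(mode)
  if (threshold <= baseline) stop("'threshold' must exceed 'baseline'")
  if (any(time_to_threshold <= 0)) stop("'time_to_threshold' must be positive")
  if (!all(c("easy", "hard") %in% names(time_to_threshold))) {
    stop("'time_to_threshold' needs named entries 'easy' and 'hard'")
  }
  if (time_to_threshold[["hard"]] <= time_to_threshold[["easy"]]) {
    stop("hard decisions must take longer to reach threshold than easy ones")
  }
  structure(list(baseline = baseline, threshold = threshold,
                 time_to_threshold = time_to_threshold,
                 maintenance_until = maintenance_until, mode = mode,
                 decay_tau = decay_tau),
            class = "firing_params")
}

#' Simulated firing-rate time course
#'
#' Builds the schematic firing profile for one difficulty and response
#' condition: a linear ramp from baseline to threshold over the
#' time-to-threshold, then (i) in the RT condition an immediate return
#' toward baseline (the response is given at threshold crossing); (ii) in
#' the DR condition, maintenance at threshold until `maintenance_until`
#' for an accumulate-and-maintain neuron, or an immediate return for an
#' accumulate-only neuron. The cue must not precede the threshold
#' crossing; the prediction assumes accumulation completes before the
#' delay cue.
#'
#' @param params a [firing_params()].
#' @param difficulty `"easy"` or `"hard"`.
#' @param condition `"RT"` or `"DR"`.
#' @param dt time step, seconds.
#' @param duration total profile duration, seconds; default covers the
#'   maintenance window plus one second.
#' @return object of class `firing_profile` with fields `dt`, `t`,
#'   `values` (Hz) and `baseline`.
#' @export
firing_profile <- function(params, difficulty = c("easy", "hard"),
                           condition = c("RT", "DR"), dt = 0.01,
                           duration = NULL) {
  stopifnot(inherits(params, "firing_params"))
  difficulty <- match.arg(difficulty)
  condition <- match.arg(condition)
  ttt <- params$time_to_threshold[[difficulty]]
  if (condition == "DR" && params$maintenance_until < ttt) {
    stop("response cue at ", params$maintenance_until,
         " s precedes threshold crossing at ", ttt,
         " s; accumulation must complete before the delay cue")
  }
  if (is.null(duration)) duration <- params$maintenance_until + 1
  t <- seq(0, duration, by = dt)
  hold_until <- if (condition == "DR" && params$mode == "accumulate_maintain") {
    params$maintenance_until
  } else {
    ttt
  }
  ramp <- params$baseline + (params$threshold - params$baseline) * t / ttt
  vals <- ifelse(t <= ttt, ramp,
                 ifelse(t <= hold_until, params$threshold, params$baseline))
  if (params$decay_tau > 0) {
    post <- t > hold_until
    vals[post] <- params$baseline + (params$threshold - params$baseline) *
      exp(-(t[post] - hold_until) / params$decay_tau)
  }
  structure(list(dt = dt, t = t, values = vals, baseline = params$baseline),
            class = "firing_profile")
}

#' HRF parameters (canonical double gamma)
#'
#' Community-standard values: peak delay 6 s, undershoot delay 16 s, unit
#' dispersions, peak:undershoot ratio 6, 32 s kernel.
#'
#' @param peak_delay,undershoot_delay gamma delays, seconds.
#' @param peak_dispersion,undershoot_dispersion gamma dispersions.
#' @param peak_undershoot_ratio ratio of peak to undershoot amplitude.
#' @param kernel_length kernel support, seconds.
#' @return object of class `hrf_params`.
#' @export
hrf_params <- function(peak_delay = 6, undershoot_delay = 16,
                       peak_dispersion = 1, undershoot_dispersion = 1,
                       peak_undershoot_ratio = 6, kernel_length = 32) {
  vals <- c(peak_delay, undershoot_delay, peak_dispersion,
            undershoot_dispersion, peak_undershoot_ratio, kernel_length)
  if (any(vals <= 0)) stop("all HRF parameters must be positive")
  structure(list(peak_delay = peak_delay, undershoot_delay = undershoot_delay,
                 peak_dispersion = peak_dispersion,
                 undershoot_dispersion = undershoot_dispersion,
                 peak_undershoot_ratio = peak_undershoot_ratio,
                 kernel_length = kernel_length),
            class = "hrf_params")
}

#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma density shapes (peak minus undershoot scaled by
#' the peak:undershoot ratio), sampled at step `dt` over the kernel length
#' and scaled to unit peak.
#'
#' @param dt sampling step, seconds.
#' @param hrf an [hrf_params()].
#' @return numeric kernel vector (max = 1) carrying its sampling step as
#'   attribute `dt`.
#' @export
canonical_hrf <- function(dt, hrf = hrf_params()) {
  if (dt <= 0) stop("'dt' must be positive")
  stopifnot(inherits(hrf, "hrf_params"))
  t <- seq(0, hrf$kernel_length, by = dt)
  peak <- dgamma(t, shape = hrf$peak_delay / hrf$peak_dispersion,
                 scale = hrf$peak_dispersion)
  under <- dgamma(t, shape = hrf$undershoot_delay / hrf$undershoot_dispersion,
                  scale = hrf$undershoot_dispersion)
  k <- peak - under / hrf$peak_undershoot_ratio
  structure(k / max(k), dt = dt)
}

#' Predicted BOLD response of a firing profile
#'
#' Discrete linear convolution of the baseline-subtracted firing profile
#' with an HRF kernel sampled on the same grid. Linear by construction:
#' additive and homogeneous in the profile deviation from baseline.
#'
#' @param profile a [firing_profile()].
#' @param kernel HRF kernel from [canonical_hrf()] evaluated at the
#'   profile's `dt`.
#' @param kernel_dt the `dt` at which the kernel was sampled; defaults to
#'   the kernel's `dt` attribute and must match the profile's.
#' @return object of class `bold_curve` with `dt`, `t`, `values` (a.u.).
#' @export
predict_bold <- function(profile, kernel,
                         kernel_dt = attr(kernel, "dt") %||% profile$dt) {
  stopifnot(inherits(profile, "firing_profile"))
  if (!isTRUE(all.equal(kernel_dt, profile$dt))) {
    stop("profile and kernel must share the same time step")
  }
  dev <- profile$values - profile$baseline
  vals <- convolve(dev, rev(as.numeric(kernel)), type = "open")
  vals <- vals[seq_len(length(dev) + length(kernel) - 1)]
  structure(list(dt = profile$dt,
                 t = seq(0, by = profile$dt, length.out = length(vals)),
                 values = vals),
            class = "bold_curve")
}

#' Response-mode by difficulty crossover summary
#'
#' Summarizes four predicted BOLD curves by their integrated amplitude and
#' reports the two contrasts of interest: (hard - easy) in the RT
#' condition and (easy - hard) in the DR condition. A combined
#' accumulation-and-maintenance region predicts both to be positive (the
#' crossover interaction); an accumulate-only region predicts hard > easy
#' in both conditions.
#'
#' @param bold_easy_rt,bold_hard_rt,bold_easy_dr,bold_hard_dr
#'   `bold_curve` objects on one common grid.
#' @param summary `"integral"` (time-integral of the curve; the GLM-style
#'   effect scales with integrated activity) or `"peak"`.
#' @return list of class `interaction_summary`: per-condition amplitudes,
#'   `rt_hard_minus_easy`, `dr_easy_minus_hard`, and logical `crossover`.
#' @export
crossover_summary <- function(bold_easy_rt, bold_hard_rt, bold_easy_dr,
                              bold_hard_dr, summary = c("integral", "peak")) {
  summary <- match.arg(summary)
  curves <- list(easy_rt = bold_easy_rt, hard_rt = bold_hard_rt,
                 easy_dr = bold_easy_dr, hard_dr = bold_hard_dr)
  dts <- vapply(curves, function(x) x$dt, numeric(1))
  if (length(unique(dts)) != 1) stop("curves must share one time grid")
  amp <- vapply(curves, function(x) {
    if (summary == "integral") sum(x$values) * x$dt else max(x$values)
  }, numeric(1))
  d_rt <- amp[["hard_rt"]] - amp[["easy_rt"]]
  d_dr <- amp[["easy_dr"]] - amp[["hard_dr"]]
  structure(list(amplitude = amp, rt_hard_minus_easy = d_rt,
                 dr_easy_minus_hard = d_dr,
                 crossover = d_rt > 0 && d_dr > 0),
            class = "interaction_summary")
}

#' @export
print.interaction_summary <- function(x, ...) {
  cat(sprintf("RT hard-easy: %.3f, DR easy-hard: %.3f -> crossover: %s\n",
              x$rt_hard_minus_easy, x$dr_easy_minus_hard, x$crossover))
  invisible(x)
}
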