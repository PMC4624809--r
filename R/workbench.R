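#' Run configuration for the full synthetic study
#'
#' Bundles everything a reproduction run needs: the experimental design,
#' the generating parameters for every simulator, MCMC budgets, seeds and
#' the output directory. Every stochastic stage receives an explicit seed
#' derived from `seed` so reruns are byte-identical.
#'
#' @param design an [experiment_design()].
#' @param hier_params a [hier_behavior_params()]; the delayed-response
#'   dataset uses accuracies raised by `dr_acc_shift`.
#' @param dr_acc_shift accuracy increase in the DR condition (the delayed
#'   response removes the speed pressure of responding mid-accumulation).
#' @param ddm_params a [ddm_params()] for the DDM-based dataset.
#' @param firing a [firing_params()]; the accumulate-only variant is
#'   derived from it.
#' @param corpus a [corpus_spec()] or `NULL` to skip the meta-analysis
#'   stage.
#' @param grid voxel grid for the meta-analysis stage.
#' @param mcmc_behavior,mcmc_ddm [mcmc_config()]s per model family.
#' @param trials_per_level trials per subject and level for the
#'   hierarchical simulator.
#' @param ddm_models which DDM variants to fit and rank by DIC.
#' @param seed master seed.
#' @param out_dir output directory (created if missing).
#' @return list of class `run_config`.
#' @export
run_config <- function(design = experiment_design(),
                       hier_params = hier_behavior_params(),
                       dr_acc_shift = 0.07,
                       ddm_params = accumaint::ddm_params(
                         v = c(2.2, 1.8, 1.0, 0.6), a = 1.5, t0 = 0.3),
                       firing = firing_params(),
                       corpus = NULL,
                       grid = voxel_grid(c(16, 16, 16), spacing = 6,
                                         origin = c(-45, -45, -45)),
                       mcmc_behavior = mcmc_config(),
                       mcmc_ddm = mcmc_config(),
                       trials_per_level = 84,
                       ddm_models = c("m1", "m2", "m3", "m4"),
                       seed = 1,
                       out_dir = tempfile("accumaint_run_")) {
  structure(list(design = design, hier_params = hier_params,
                 dr_acc_shift = dr_acc_shift, ddm_params = ddm_params,
                 firing = firing, corpus = corpus, grid = grid,
                 mcmc_behavior = mcmc_behavior, mcmc_ddm = mcmc_ddm,
                 trials_per_level = trials_per_level,
                 ddm_models = ddm_models, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

stage <- function(name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  message(sprintf("[%s] done in %.1f s", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

contrast_report <- function(chain_a, chain_b, label) {
  diff <- chain_a - chain_b
  iv <- hdi(diff)
  list(contrast = label, prob_greater = prob_greater(chain_a, chain_b),
       hdi_low = iv[1], hdi_high = iv[2])
}

#' Reproduce the behavioral study on synthetic data
#'
#' Simulates the behavioral datasets, fits the hierarchical accuracy and
#' response-time models and the requested DDM variants, and writes trial
#' tables, chain CSVs and a summary JSON with, per contrast, the
#' posterior probability of a positive difference, its 95% HDI and the
#' maximum group-level R-hat, plus the DIC ranking of the DDM variants.
#'
#' @param cfg a [run_config()].
#' @return the summary list, invisibly; artifacts under `cfg$out_dir`.
#' @export
run_behavioral_study <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed
  message(sprintf("run_behavioral_study: seed %d -> %s", seed, cfg$out_dir))

  rt_trials <- stage("simulate RT behavior", simulate_hier_behavior(
    cfg$design, cfg$hier_params, seed = seed,
    condition = "RT", trials_per_level = cfg$trials_per_level))
  dr_params <- cfg$hier_params
  dr_params$acc_mean <- pmin(dr_params$acc_mean + cfg$dr_acc_shift, 0.99)
  dr_trials <- stage("simulate DR behavior", simulate_hier_behavior(
    cfg$design, dr_params, seed = seed + 1,
    condition = "DR", trials_per_level = cfg$trials_per_level))
  ddm_trials <- stage("simulate DDM dataset", simulate_ddm_dataset(
    cfg$design, cfg$ddm_params, seed = seed + 2))
  write_trial_table(rt_trials, file.path(cfg$out_dir, "trials_rt.csv"))
  write_trial_table(dr_trials, file.path(cfg$out_dir, "trials_dr.csv"))
  write_trial_table(ddm_trials, file.path(cfg$out_dir, "trials_ddm.csv"))

  acc_rt <- stage("fit accuracy (RT)", fit_accuracy_model(
    rt_trials, "RT", cfg$mcmc_behavior, seed = seed + 10))
  acc_dr <- stage("fit accuracy (DR)", fit_accuracy_model(
    dr_trials, "DR", cfg$mcmc_behavior, seed = seed + 11))
  rt_fit <- stage("fit RT model (RT)", fit_rt_model(
    rt_trials, "RT", cfg$mcmc_behavior, seed = seed + 12))
  write_chains_csv(acc_rt, file.path(cfg$out_dir, "chains_accuracy_rt.csv"))
  write_chains_csv(acc_dr, file.path(cfg$out_dir, "chains_accuracy_dr.csv"))
  write_chains_csv(rt_fit, file.path(cfg$out_dir, "chains_rt.csv"))

  g <- function(fit, params) grouped_parameter_chain(fit, params)
  contrasts <- list(
    contrast_report(g(acc_rt, c("acc_mean[1]", "acc_mean[2]")),
                    g(acc_rt, c("acc_mean[3]", "acc_mean[4]")),
                    "accuracy: easy > hard (RT)"),
    contrast_report(g(acc_dr, sprintf("acc_mean[%d]", 1:4)),
                    g(acc_rt, sprintf("acc_mean[%d]", 1:4)),
                    "accuracy: DR > RT"),
    contrast_report(g(rt_fit, c("rt_mean[3]", "rt_mean[4]")),
                    g(rt_fit, c("rt_mean[1]", "rt_mean[2]")),
                    "response time: hard > easy (RT)"))

  rhat_max <- max(gelman_rubin(acc_rt, acc_rt$group_params),
                  gelman_rubin(acc_dr, acc_dr$group_params),
                  gelman_rubin(rt_fit, rt_fit$group_params))

  fits <- list()
  for (m in cfg$ddm_models) {
    fits[[m]] <- stage(sprintf("fit DDM %s", m), fit_hddm(
      ddm_trials, ddm_model_spec(m), cfg$mcmc_ddm, seed = seed + 20))
  }
  dics <- stage("DIC ranking", dic_table(fits))
  first_fit <- fits[[cfg$ddm_models[1]]]
  ddm_rhat <- if (nrow(first_fit$samples[[1]]) >= 2) {
    max(gelman_rubin(first_fit, first_fit$group_params))
  } else {
    NA_real_  # single-chain run: the diagnostic is undefined
  }

  summary <- list(schema = "accumaint/behavioral-report-v1", seed = seed,
                  contrasts = contrasts, max_rhat_behavior = rhat_max,
                  max_rhat_ddm = ddm_rhat,
                  dic_ranking = dics)
  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, dataframe = "rows")
  invisible(summary)
}

#' Forward BOLD predictions and the synthetic meta-analysis
#'
#' Writes the predicted firing/BOLD curves for both response mechanisms
#' (accumulate-and-maintain vs accumulate-only) with their crossover
#' flags, then generates a synthetic corpus, plants a contrast map at the
#' planted associations and writes the ranked evidence-score table.
#'
#' @param cfg a [run_config()] with a non-`NULL` `corpus`.
#' @return the report list, invisibly; artifacts under `cfg$out_dir`.
#' @export
run_prediction_and_meta <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  message(sprintf("run_prediction_and_meta: seed %d -> %s", cfg$seed,
                  cfg$out_dir))

  modes <- c("accumulate_maintain", "accumulate_only")
  kern <- canonical_hrf(0.01)
  curves <- list()
  flags <- list()
  for (mode in modes) {
    fp <- cfg$firing
    fp$mode <- mode
    duration <- fp$maintenance_until + 1
    bold <- list()
    for (cond in c("RT", "DR")) {
      for (diff in c("easy", "hard")) {
        prof <- firing_profile(fp, diff, cond, dt = 0.01,
                               duration = duration)
        b <- predict_bold(prof, kern)
        bold[[paste(diff, cond, sep = "_")]] <- b
        curves[[length(curves) + 1]] <- data.frame(
          mode = mode, condition = cond, difficulty = diff, t = b$t,
          value = b$values)
      }
    }
    cs <- crossover_summary(bold$easy_RT, bold$hard_RT, bold$easy_DR,
                            bold$hard_DR)
    flags[[mode]] <- list(mode = mode, crossover = cs$crossover,
                          rt_hard_minus_easy = cs$rt_hard_minus_easy,
                          dr_easy_minus_hard = cs$dr_easy_minus_hard)
  }
  write.csv(do.call(rbind, curves),
            file.path(cfg$out_dir, "bold_curves.csv"), row.names = FALSE)

  report <- list(schema = "accumaint/prediction-meta-report-v1",
                 seed = cfg$seed, crossover = unname(flags))

  if (!is.null(cfg$corpus)) {
    corpus <- stage("generate corpus",
                    generate_meta_corpus(cfg$corpus, cfg$grid, cfg$seed + 30))
    write_corpus(corpus, file.path(cfg$out_dir, "corpus.json"))
    masks <- stage("activation masks",
                   activation_masks(corpus$foci_db, cfg$grid))
    planted <- corpus$planted
    if (!nrow(planted)) stop("corpus spec has no planted association")
    cmap <- simulate_stat_map(cfg$grid, data.frame(
      x = planted$x, y = planted$y, z = planted$z,
      peak_z = 4, fwhm_mm = 12))
    write_statmap_csv(cmap, file.path(cfg$out_dir, "contrast_map.csv"))
    scores <- stage("evidence scores",
                    evidence_scores(cmap, corpus$term_db, masks))
    write.csv(scores, file.path(cfg$out_dir, "evidence_scores.csv"),
              row.names = FALSE)
    top <- top_terms(scores)
    report$top_terms <- top$term
    report$n_terms_reported <- nrow(top)
  }
  jsonlite::write_json(report, file.path(cfg$out_dir, "prediction_report.json"),
                       auto_unbox = TRUE, digits = 10)
  invisible(report)
}
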