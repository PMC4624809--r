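#' Experimental design of the face/house discrimination task
#'
#' Describes the structure of a two-alternative forced-choice (2AFC)
#' perceptual experiment with immediate and delayed response modes: how many
#' participants, how many trials per run, which runs are reaction-time (RT)
#' and which delayed-response (DR), the phase-coherence levels that define
#' the four difficulty levels for each stimulus class, and the timing
#' windows.
#'
#' The defaults reproduce the study conditions: 18 participants; three runs
#' of 112 trials each (two RT runs, one DR run); a 1 s stimulus window; a
#' 500 ms cued delay followed by a 500 ms response window in the DR
#' condition. Difficulty levels are ordered from easiest (1) to hardest (4),
#' with per-class proportion coherences (easy house 0.54/0.51, hard house
#' 0.465/0.437; easy face 0.53/0.50, hard face 0.445/0.427).
#'
#' @param n_subjects number of participants (>= 1).
#' @param trials_per_run trials in each run (>= 1).
#' @param runs character vector of run conditions, each `"RT"` or `"DR"`.
#' @param coherence_levels data frame with columns `level` (1..4), `face`
#'   and `house` (proportion coherence in (0, 1)), ordered easiest first.
#' @param stimulus_window_s stimulus presentation window in seconds (the
#'   response deadline in the RT condition).
#' @param dr_delay_s cued delay between stimulus offset and response cue in
#'   the DR condition, seconds.
#' @param dr_response_window_s response window after the cue in the DR
#'   condition, seconds.
#'
#' @return An object of class `experiment_design`.
#' @examples
#' d <- experiment_design(n_subjects = 4)
#' d$trials_per_run
#' @export
experiment_design <- function(n_subjects = 18,
                              trials_per_run = 112,
                              runs = c("RT", "DR", "RT"),
                              coherence_levels = default_coherence_levels(),
                              stimulus_window_s = 1,
                              dr_delay_s = 0.5,
                              dr_response_window_s = 0.5) {
  stopifnot(is.numeric(n_subjects), length(n_subjects) == 1)
  if (n_subjects < 0) stop("'n_subjects' must be >= 0")
  if (trials_per_run < 1) stop("'trials_per_run' must be >= 1")
  runs <- match.arg(runs, c("RT", "DR"), several.ok = TRUE)
  stopifnot(is.data.frame(coherence_levels),
            all(c("level", "face", "house") %in% names(coherence_levels)))
  coh <- unlist(coherence_levels[, c("face", "house")])
  if (any(coh <= 0 | coh >= 1)) {
    stop("coherence values must be proportions in (0, 1)")
  }
  if (stimulus_window_s <= 0 || dr_delay_s <= 0 || dr_response_window_s <= 0) {
    stop("all timing windows must be positive")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 trials_per_run = as.integer(trials_per_run),
                 runs = runs,
                 coherence_levels = coherence_levels,
                 stimulus_window_s = stimulus_window_s,
                 dr_delay_s = dr_delay_s,
                 dr_response_window_s = dr_response_window_s),
            class = "experiment_design")
}

#' Default phase-coherence table
#'
#' Four difficulty levels (1 = easiest) with proportion coherence per
#' stimulus class. Coherences differ slightly between classes so that
#' face and house accuracies are aligned.
#'
#' @return data frame with columns `level`, `face`, `house`.
#' @export
default_coherence_levels <- function() {
  data.frame(level = 1:4,
             face = c(0.530, 0.500, 0.445, 0.427),
             house = c(0.540, 0.510, 0.465, 0.437))
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("2AFC experiment design\n")
  cat(sprintf("  subjects: %d, runs: %s, trials/run: %d\n",
              x$n_subjects, paste(x$runs, collapse = " "), x$trials_per_run))
  cat(sprintf("  stimulus window %.3g s; DR delay %.3g s, response window %.3g s\n",
              x$stimulus_window_s, x$dr_delay_s, x$dr_response_window_s))
  invisible(x)
}

trial_table_columns <- c("subject", "condition", "coherence_level",
                         "stimulus", "choice", "correct", "rt")

# balanced level x stimulus assignment for one run, shuffled
run_trial_layout <- function(trials_per_run, n_levels = 4) {
  cells <- expand.grid(level = seq_len(n_levels),
                       stimulus = c("face", "house"),
                       stringsAsFactors = FALSE)
  reps <- ceiling(trials_per_run / nrow(cells))
  idx <- rep(seq_len(nrow(cells)), reps)[seq_len(trials_per_run)]
  cells[sample(idx), , drop = FALSE]
}

#' Write / read a trial table as CSV
#'
#' The canonical on-disk format keeps the columns
#' `subject,condition,coherence_level,stimulus,choice,correct,rt`; extra
#' in-memory columns (for example the DR cue onset) are dropped on write.
#'
#' @param trials a trial table data frame.
#' @param path file path.
#' @return `read_trial_table` returns the trial table data frame.
#' @export
write_trial_table <- function(trials, path) {
  stopifnot(all(trial_table_columns %in% names(trials)))
  write.csv(trials[, trial_table_columns], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(trial_table_columns %in% names(x)))
  x
}
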