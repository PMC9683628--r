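# Behavioral summaries over simulated cohorts: learning curves of expected
# reward probability and of the number of features selected, by game type
# and trial index, plus change-in-choice switch identification.

# per-(session, type, trial) means of a per-trial statistic, then
# mean +/- s.e.m. across sessions
.curve_table <- function(cohort, stat_fn) {
  rows <- list()
  for (s in cohort) {
    for (g in s$games) {
      rows[[length(rows) + 1L]] <- data.frame(
        session = s$id,
        complexity = g$spec$complexity,
        knowledge = if (g$spec$known) "known" else "unknown",
        trial = seq_along(g$rewards),
        value = stat_fn(g))
    }
  }
  long <- do.call(rbind, rows)
  per_session <- stats::aggregate(value ~ session + complexity + knowledge +
                                    trial, data = long, FUN = mean)
  agg <- stats::aggregate(value ~ complexity + knowledge + trial,
                          data = per_session,
                          FUN = function(x) c(mean = mean(x),
                                              sem = if (length(x) > 1)
                                                sd(x) / sqrt(length(x))
                                                else NA_real_,
                                              n = length(x)))
  out <- data.frame(agg[c("complexity", "knowledge", "trial")],
                    mean = agg$value[, "mean"], sem = agg$value[, "sem"],
                    n_sessions = agg$value[, "n"])
  out[order(out$knowledge, out$complexity, out$trial), ]
}

#' Learning curve of expected reward probability
#'
#' The per-trial statistic is the reward probability of the realized
#' stimulus under the game's true rule (the expected probability given the
#' number of rewarding features configured, not the realized 0/1 outcome),
#' averaged within game type per session, then mean and s.e.m. across
#' sessions.
#'
#' @param cohort A list of sessions (e.g. from [simulate_cohort()]).
#' @return Data.frame with columns complexity, knowledge, trial, mean, sem,
#'   n_sessions.
#' @export
reward_prob_curve <- function(cohort) {
  .curve_table(cohort, function(g) {
    vapply(seq_along(g$rewards),
           function(t) reward_probability(g$spec$true_rule, g$stimuli[t, ]),
           numeric(1))
  })
}

#' Learning curve of the number of features selected
#'
#' Per-trial count of dimensions the agent selected (0-3), aggregated as in
#' [reward_prob_curve()].
#'
#' @param cohort A list of sessions.
#' @return Data.frame with columns complexity, knowledge, trial, mean, sem,
#'   n_sessions.
#' @export
features_selected_curve <- function(cohort) {
  .curve_table(cohort, function(g) as.numeric(rowSums(g$choices > 0L)))
}

#' Identify switch trials from choices
#'
#' A trial is a switch trial when its configuration differs from the
#' previous trial's configuration in any dimension; the first trial is never
#' flagged. This is the behavioral (observable) definition, independent of
#' any latent hypothesis inference.
#'
#' @param choices T x 3 integer configuration matrix, or a played `game`.
#' @return Logical vector of length T.
#' @export
identify_switch_trials <- function(choices) {
  if (inherits(choices, "game")) choices <- choices$choices
  choices <- rbind(choices)
  T_ <- nrow(choices)
  if (T_ == 1L) return(FALSE)
  c(FALSE, rowSums(choices[-1L, , drop = FALSE] !=
                     choices[-T_, , drop = FALSE]) > 0L)
}
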