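# Bayesian rule learning: an exact posterior over the hint-consistent rule
# space, updated from each realized stimulus and reward, with expected reward
# for each configuration computed by marginalizing the reward law over the
# posterior and choices made by softmax on that expected reward. The model is
# greedy (maximizes this trial's expected reward), not game-optimal.

#' Parameters of the Bayesian rule-learning model
#'
#' @param beta Softmax inverse temperature (>= 0).
#' @return A `bayes_params` list.
#' @export
bayes_params <- function(beta) {
  stopifnot(beta >= 0)
  structure(list(beta = beta), class = "bayes_params")
}

#' Uniform initial belief over the hint-consistent rules
#'
#' @param hint 1, 2, 3 (known games) or `"unknown"` (all 63 rules).
#' @return A `belief` list with `support` (indices into the canonical 63-rule
#'   set) and `probs` (uniform probabilities).
#' @export
bayes_init_belief <- function(hint = "unknown") {
  d <- rule_dims()
  support <- if (identical(hint, "unknown")) seq_along(d) else
    which(d == hint)
  structure(list(support = support,
                 probs = rep(1 / length(support), length(support))),
            class = "belief")
}

#' Bayes update of the belief from one outcome
#'
#' Each rule's probability is multiplied by the likelihood of the observed
#' reward given the realized stimulus (the full three-feature outcome
#' context) and renormalized. Likelihoods lie in \[0.2, 0.8\], so the
#' posterior can never degenerate.
#'
#' @param belief A belief from [bayes_init_belief()].
#' @param stimulus Realized stimulus (length-3 vector, entries 1..3).
#' @param reward 0 or 1.
#' @return Updated belief.
#' @export
bayes_update_belief <- function(belief, stimulus, reward) {
  rp <- rp_rule_stimulus()[belief$support, stimulus_index(stimulus)]
  lik <- if (reward == 1) rp else 1 - rp
  p <- belief$probs * lik
  belief$probs <- p / sum(p)
  belief
}

#' Posterior-expected reward for every configuration
#'
#' Marginalizes the reward law over the belief: for each of the 64
#' configurations, the belief-weighted expected reward under each rule (with
#' unselected dimensions filled uniformly by the computer).
#'
#' @param belief A belief.
#' @return Numeric vector of length 64 in canonical configuration order.
#' @export
bayes_expected_rewards <- function(belief) {
  as.numeric(belief$probs %*% er_rule_config()[belief$support, , drop = FALSE])
}

#' Session log-likelihood under the Bayesian rule learner
#'
#' The belief resets at each game start using that game's hint; each observed
#' choice is scored by softmax(beta * ER) before the belief is updated with
#' the trial's realized stimulus and reward.
#'
#' @param session A [new_session()] object.
#' @param params A [bayes_params()] object.
#' @param games Indices of games to include (default all).
#' @return List with `total`, `by_game`, `n_trials` as in
#'   [rl_session_loglik()].
#' @export
bayes_session_loglik <- function(session, params, games = NULL) {
  if (is.null(games)) games <- seq_along(session$games)
  er_mat <- er_rule_config()
  rp_mat <- rp_rule_stimulus()
  by_game <- vapply(session$games[games], function(gm) {
    support <- bayes_init_belief(game_hint(gm$spec))$support
    bayes_game_ll_cpp(gm$choice_idx, gm$stim_idx, gm$rewards, params$beta,
                      support, er_mat, rp_mat)
  }, numeric(1))
  n_trials <- vapply(session$games[games],
                     function(g) length(g$rewards), integer(1))
  list(total = sum(by_game), by_game = by_game, n_trials = n_trials)
}

#' Simulate one game with the Bayesian rule-learning agent
#'
#' @param spec A [game_spec()].
#' @param params A [bayes_params()] object.
#' @return A played `game`. Uses R's global RNG.
#' @export
bayes_simulate_game <- function(spec, params) {
  g <- configurations()
  T_ <- spec$n_trials
  choices <- matrix(0L, T_, 3)
  stims <- matrix(0L, T_, 3)
  rewards <- integer(T_)
  b <- bayes_init_belief(game_hint(spec))
  for (t in seq_len(T_)) {
    p <- softmax_probs(bayes_expected_rewards(b), params$beta)
    ci <- sample.int(64L, 1L, prob = p)
    choices[t, ] <- g[ci, ]
    stims[t, ] <- realize_stimulus(choices[t, ])
    rewards[t] <- rbinom(1L, 1L, reward_probability(spec$true_rule,
                                                    stims[t, ]))
    b <- bayes_update_belief(b, stims[t, ], rewards[t])
  }
  new_game(spec, choices, stims, rewards)
}
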