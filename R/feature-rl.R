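# Feature-based reinforcement learning with value decay. The agent maintains
# a value V[i, j] for feature j of dimension i; the expected reward of a
# configuration is the sum of its feature values (dimension mean for
# unselected dimensions), choices are softmax in expected reward, and values
# update by a Rescorla-Wagner rule with separate learning rates for
# self-selected vs computer-filled features and multiplicative decay of
# features absent from the realized stimulus.

#' Parameters of the feature RL with decay model
#'
#' @param beta Softmax inverse temperature (>= 0).
#' @param eta_s Learning rate for features the agent selected, in \[0, 1\].
#' @param eta_r Learning rate for computer-filled features, in \[0, 1\].
#' @param decay Per-trial multiplicative decay toward zero for the six
#'   features absent from the realized stimulus, in \[0, 1\] (1 = no decay).
#' @return An `rl_params` list.
#' @export
rl_params <- function(beta, eta_s, eta_r, decay) {
  stopifnot(beta >= 0, eta_s >= 0, eta_s <= 1, eta_r >= 0, eta_r <= 1,
            decay >= 0, decay <= 1)
  structure(list(beta = beta, eta_s = eta_s, eta_r = eta_r, decay = decay),
            class = "rl_params")
}

#' Initial feature values
#' @return 3 x 3 zero matrix (dimensions x features).
#' @export
rl_init_values <- function() matrix(0, 3, 3)

#' Expected reward of one configuration under feature values
#'
#' Sum over dimensions of the selected feature's value, using the dimension's
#' mean value for unselected dimensions.
#'
#' @param values 3 x 3 feature-value matrix.
#' @param choice Integer vector of length 3 (0 = unselected).
#' @return Scalar expected reward.
#' @export
rl_expected_reward <- function(values, choice) {
  v <- 0
  for (i in 1:3) {
    v <- v + if (choice[i] > 0L) values[i, choice[i]] else mean(values[i, ])
  }
  v
}

# expected reward for all 64 canonical configurations (vectorized)
rl_er_all <- function(values) {
  g <- configurations()
  a <- cbind(rowMeans(values), values)  # column j+1 = feature j, column 1 = mean
  a[1L, g[, 1] + 1L] + a[2L, g[, 2] + 1L] + a[3L, g[, 3] + 1L]
}

# overflow-safe softmax of beta * er
softmax_probs <- function(er, beta) {
  z <- beta * er
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Softmax choice probabilities over the 64 configurations
#'
#' @param values 3 x 3 feature-value matrix.
#' @param beta Inverse temperature (>= 0).
#' @return Probability vector of length 64 in canonical configuration order.
#' @export
rl_choice_probabilities <- function(values, beta) {
  stopifnot(beta >= 0)
  softmax_probs(rl_er_all(values), beta)
}

#' One Rescorla-Wagner update with decay
#'
#' The prediction error is the reward minus the expected reward of the
#' *choice* (dimension means filling unselected dimensions); the update lands
#' on the three features of the realized stimulus, with rate `eta_s` on
#' dimensions the agent selected and `eta_r` on computer-filled dimensions.
#' The six features absent from the stimulus are multiplied by `decay`.
#'
#' @param values 3 x 3 feature-value matrix.
#' @param choice,stimulus,reward The trial's configuration, realized
#'   stimulus, and 0/1 reward.
#' @param params An [rl_params()] object.
#' @return Updated 3 x 3 value matrix.
#' @export
rl_update <- function(values, choice, stimulus, reward, params) {
  sel <- choice > 0L
  if (!all(stimulus[sel] == choice[sel])) {
    stop("stimulus inconsistent with choice", call. = FALSE)
  }
  pe <- reward - rl_expected_reward(values, choice)
  new <- values * params$decay
  for (i in 1:3) {
    eta <- if (sel[i]) params$eta_s else params$eta_r
    new[i, stimulus[i]] <- values[i, stimulus[i]] + eta * pe
  }
  new
}

#' Session log-likelihood under the feature RL model
#'
#' Values reset to zero at the start of every game (rules change between
#' games); each observed choice is scored by the softmax policy before the
#' update from that trial's outcome.
#'
#' @param session A [new_session()] object.
#' @param params An [rl_params()] object.
#' @param games Indices of games to include (default all).
#' @return List with `total` log-likelihood, per-game vector `by_game`, and
#'   per-game trial counts `n_trials`.
#' @export
rl_session_loglik <- function(session, params, games = NULL) {
  if (is.null(games)) games <- seq_along(session$games)
  cfg <- configurations()
  by_game <- vapply(session$games[games], function(gm) {
    rl_game_ll_cpp(cfg, gm$choices, gm$choice_idx, gm$stimuli, gm$rewards,
                   params$beta, params$eta_s, params$eta_r, params$decay)
  }, numeric(1))
  n_trials <- vapply(session$games[games],
                     function(g) length(g$rewards), integer(1))
  list(total = sum(by_game), by_game = by_game, n_trials = n_trials)
}

#' Simulate one game with the feature RL agent
#'
#' @param spec A [game_spec()].
#' @param params An [rl_params()] object.
#' @return A played `game` (see [new_game()]). Uses R's global RNG.
#' @export
rl_simulate_game <- function(spec, params) {
  g <- configurations()
  T_ <- spec$n_trials
  choices <- matrix(0L, T_, 3)
  stims <- matrix(0L, T_, 3)
  rewards <- integer(T_)
  v <- rl_init_values()
  for (t in seq_len(T_)) {
    p <- rl_choice_probabilities(v, params$beta)
    ci <- sample.int(64L, 1L, prob = p)
    choices[t, ] <- g[ci, ]
    stims[t, ] <- realize_stimulus(choices[t, ])
    rewards[t] <- rbinom(1L, 1L, reward_probability(spec$true_rule,
                                                    stims[t, ]))
    v <- rl_update(v, choices[t, ], stims[t, ], rewards[t], params)
  }
  new_game(spec, choices, stims, rewards)
}
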