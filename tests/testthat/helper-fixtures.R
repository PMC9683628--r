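# Shared fixtures: small hand-specified games and simulated sessions.

# fixed 3-trial game used for the feature-RL hand trace
fixture_rl_game <- function() {
  new_game(game_spec(1, TRUE, c(2L, 0L, 0L), n_trials = 3L),
           choices = rbind(c(1L, 0L, 0L), c(1L, 2L, 0L), c(0L, 0L, 0L)),
           stims = rbind(c(1L, 3L, 2L), c(1L, 2L, 2L), c(2L, 1L, 3L)),
           rewards = c(1L, 0L, 1L))
}

# fixed 2-trial game used for the Bayesian hand trace
fixture_bayes_game <- function() {
  new_game(game_spec(2, TRUE, c(1L, 2L, 0L), n_trials = 2L),
           choices = rbind(c(1L, 0L, 0L), c(1L, 2L, 0L)),
           stims = rbind(c(1L, 3L, 2L), c(1L, 2L, 2L)),
           rewards = c(1L, 1L))
}

# one-game session wrapper
fixture_session <- function(game) new_session("fix", list(game))

# simulate a session with a reduced design
sim_mini_session <- function(model, par, n_per_type = 1L, n_trials = 10L,
                             seed = 1L, id = "mini") {
  set.seed(seed)
  simulate_session(generate_design(n_per_type, n_trials), model, par, id)
}

# randomized short known-1D games (9-rule space) for the path-enumeration
# oracle battery; trials drawn from an arbitrary stochastic policy so the
# battery covers lapse and hypothesis-consistent choices alike
random_short_game <- function(n_trials = 4L, complexity = 1L, known = TRUE) {
  spec <- game_spec(complexity, known, n_trials = n_trials)
  cfg <- configurations()
  one_dim <- which(rowSums(cfg > 0L) <= 1L)  # favor sparse choices
  idx <- sample(c(one_dim, seq_len(64L)), n_trials, replace = TRUE)
  choices <- cfg[idx, , drop = FALSE]
  stims <- t(apply(choices, 1, realize_stimulus))
  rewards <- vapply(seq_len(n_trials), function(t) {
    rbinom(1L, 1L, reward_probability(spec$true_rule, stims[t, ]))
  }, integer(1))
  new_game(spec, choices, stims, rewards)
}
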